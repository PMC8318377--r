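Package: avreplay
Title: Reactivation and Replay Analysis for Model-Based Aversive Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale analysis of model-based aversive learning
    with neural reactivation and replay. Implements an asymmetric
    Rescorla-Wagner learning model with a generalization parameter,
    hierarchical Bayesian fitting and WAIC model comparison; stimulus
    decoding with temporal generalization and one-versus-rest state
    classifiers; lag-resolved sequenceness (replay) detection in sliding
    windows; hierarchical latent Gaussian-process regression of replay time
    courses; and regression-based coupling of band-limited power to
    reactivation strength. A synthetic-data module generates localizer and
    task epochs with injectable reactivation and replay events, so every
    analysis can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
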