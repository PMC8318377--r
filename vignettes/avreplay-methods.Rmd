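---
title: "Methods: models, estimators and design choices in avreplay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in avreplay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(avreplay)
```

`avreplay` is a desk-scale pipeline for studying model-based aversive
learning with neural reactivation and replay. It covers five connected
analyses — a reinforcement-learning model of avoidance behavior, stimulus
decoding from multichannel sensor data, lag-resolved sequenceness (replay)
detection, hierarchical latent Gaussian-process regression (HLGPR) of
replay time courses, and regression-based coupling of band-limited power
to reactivation — together with a synthetic-data module that generates
every input with known ground truth. This vignette documents the models,
the estimators behind each function, the defaults and their rationale,
and the limits of what the synthetic validation can show.

## The task and its state space

The task is an aversive reversal-learning task on a map of 14 states
(`A`–`N`) arranged in four 4-state arms. Two *learning* arms
(`B>F>J>M`, `C>G>K>N`) end in terminal states whose shock probabilities
drift over trials; choosing one plays out the path and shows the
outcome. Two *generalization* arms (`A>E>I>M`, `D>H>L>N`) share those
same terminal states, but their outcomes are never shown — choices there
can only be guided by values learned on the other arms, i.e. by
model-based inference. 28% of the 120 trials are generalization trials.

`generate_shock_walk()` emulates the drifting shock probabilities with
two reflecting Gaussian random walks whose innovations are negatively
coupled. The original probability series is not published, only its
design features: the two series were moderately anticorrelated
(r ≈ −0.57) and each terminal state was the safer option on roughly half
of trials. The default coupling (−0.65) and symmetric starting values
(0.5, 0.5) were calibrated once by Monte-Carlo so the mean within-walk
correlation reproduces −0.57 and the safer-terminal split is ~50/50; the
walk is therefore a statistical stand-in with the stated design
properties, not a reconstruction. Bounds default to [0.05, 0.95] so that
neither terminal becomes a certain outcome, which would make learning
rates unidentifiable. The generalization-trial count uses round-half-up
(0.28 × 120 = 33.6 → 34).

## The behavioral model

Values are *shock expectancies* for the two terminal states, initialised
at 0.5 (the neutral point of the generalization transform below). On
each learning trial the chosen terminal's value is updated by a
prediction error `delta = outcome − V` (shock = 1, safe = 0) with
asymmetric learning rates: `alpha_plus` when `delta > 0` (an unexpected
shock), `alpha_minus` when `delta < 0`. Note the sign convention: under
shock = 1 coding a *positive* prediction error is a worse-than-expected
outcome, so `alpha_plus` is the "learning from danger" rate.

On generalization trials no outcome is shown and values are never
updated; instead both values are shrunk toward 0.5 by the generalization
weight `G` before entering the choice rule: `V' = 0.5 + (V − 0.5)·G`.
`G = 0` makes generalization choices random; `G = 1` makes them as
value-driven as learning-trial choices.

Choice follows a per-option softmax: each option `o` receives the score
`exp(β·u_o) / (exp(β·u_o) + exp(β·(1 − u_o)))` and the two scores are
renormalized to give the choice probability. Because values code shock
expectancy while the printed softmax increases choice probability with
its argument, the default decision value is the *safety* value
`u_o = 1 − V_o`; a `value_coding = "shock"` flag gives the literal
coding (with β free this is a reparameterization, but the safety coding
keeps β ≥ 0 interpretable as avoidance strength). The per-option score
plus renormalization reading resolves the ambiguity of how a two-option
softmax could fail to normalize: each option is first scored against its
own complement, and the two scores then need renormalizing.

### Hierarchical fitting

`fit_hierarchical()` fits four variants (asymmetric/symmetric learning
rates × with/without G) across participants. Parameters are transformed
to an unconstrained scale (logit for the rates and G, log for β), where
each participant's vector receives a Normal group prior. Fitting
alternates per-participant MAP estimation (BFGS) with EM updates of the
group mean and SD; the SD update adds the per-participant posterior
variances to the spread of the MAP estimates, so group variance is not
collapsed by the point estimates. Each participant's posterior is then
approximated by a Gaussian centred on the MAP with covariance from the
local curvature (a Laplace approximation — itself a Gaussian
approximate posterior, in the same family as variational Gaussian
approximations), from which parameter draws and pointwise
log-likelihoods are computed. Group SDs are floored at 0.1 on the
transformed scale to keep the EM stable with few participants.
Non-convergence of the EM loop is reported via a warning and the
`converged` flag.

WAIC uses the variance-based effective-parameter estimator:
`WAIC = −2(lppd − p_waic)` with `p_waic` the summed posterior variance
of the pointwise log-likelihoods.

Parameter-recovery behavior at the study scale (28 participants × 120
trials, β ~ lognormal around 5): `G` and `alpha_plus` are well
identified (r ≈ 0.75–0.9 between truth and posterior means);
`alpha_minus` is intrinsically harder — safety outcomes move values
gradually and produce fewer behavioral reversals than shocks — and its
single-cohort recovery correlation fluctuates around 0.6. The MAP
surface is unimodal (checked by multi-start optimization), so this is an
information limit of the design, not an optimizer artifact. The
acceptance test therefore averages recovery correlations over five
replicate cohorts.

The model-agnostic `consistency_index()` is the fraction of
generalization trials whose chosen terminal repeats the terminal chosen
on the most recent preceding learning trial; it is 0.5 under `G = 0`
and rises monotonically with `G`.

## Decoding

Two classifier families are trained on localizer epochs (one stimulus
per trial, 100 Hz):

* `train_binary_grid()` trains a terminal-state discriminator at each
  training time (every 10 ms up to 800 ms): standardize → PCA (50
  components) → L1 logistic regression. The penalty is chosen by random
  search over 100 half-Cauchy(γ = 5) draws with stratified 3-fold
  cross-validation. The draws are interpreted as penalty *strengths*
  (scaled per-observation, as in scikit-learn's `alpha`); ties favour
  the stronger penalty.
* `train_state_classifiers()` trains 14 one-vs-rest state classifiers at
  one training time, on a temporal embedding of ±50 ms (11 samples),
  with temporal PCA (components drawn uniformly from [30, 60], tuned
  jointly with the penalty over 100 random-search iterations) and
  balanced sample weights.

`temporal_generalization()` applies the binary grid across task time,
scoring accuracy against the *chosen* terminal per (train time × task
time) cell; below-chance cells are read as reactivation of the unchosen
state. `reactivation_timecourse()` slides the one-vs-rest embedding
along a trial epoch, yielding per-state probabilities at every usable
sample — a 6-s epoch at 100 Hz gives 590 rows because the ±5-sample
embedding trims each edge. `cluster_test_map()` provides 2D
cluster-mass permutation inference on per-participant maps (one-sample t
against chance with participant sign flipping, or across-participant
correlation with a covariate such as G, with covariate permutation),
4-connectivity, pointwise two-sided p < 0.05 cluster forming, 5000
permutations by default — conventional choices where no values are
prescribed.

A note on hyperparameter selection: the cross-validated accuracy of the
*selected* configuration is optimistically biased (winner's curse over
100 draws). Calibration checks therefore score held-out data
(`predict()` on fresh epochs), which is how the chance-level test at
snr = 0 is run.

## Sequenceness

`compute_sequenceness()` implements the cross-correlation form of
temporally delayed linear modelling: for each lag d (10–200 ms in 10-ms
steps), the forward statistic is the mean Pearson correlation, over
ordered state pairs with a task transition i → j, between state i's
reactivation series lagged by d and state j's series; the backward
statistic uses the transposed transition matrix; their difference
indexes forward-minus-reverse replay. The subtraction is the point: the
large common autocorrelation of the two directions cancels, so only the
difference is interpreted, never either direction alone.
Design choices where the source is silent: Pearson correlation (the
field convention), mean over valid transition pairs, zero-variance
series contribute correlation 0 (flagged) since a constant probability
carries no sequence evidence, and per-arm differences are averaged
*after* the forward−backward subtraction. `sliding_window_sequenceness()`
applies the statistic in 400-ms windows stepped by one sample (both
configurable), indexed by window centre; the windowed implementation is
oracle-tested against an independent brute-force loop to 1e-10.
`collapse_lags()` reduces the lag axis by mean (or max-|difference|)
over a lag band — the lag reduction ahead of HLGPR is not fully
specified by the source, so it is exposed as an explicit, configurable
step.

Antisymmetry (time-reversing the input exactly negates the difference at
every lag) and invariance to consistent state relabelling are enforced
as property tests.

## Hierarchical latent GP regression

HLGPR models per-trial sequenceness series as
`y_jt ~ N(Σ_r X_jr · β_{p(j),r}(t), σ²)` with time-varying weights
`β_{i,r}(t) = g_r(t) + d_{i,r}(t)`: a group-level curve `g_r` with a
constant-mean squared-exponential GP prior (mean μ ~ N(0, 5), kernel SD
~ Gamma(3, 5), length-scale ~ Gamma(3, 1), in seconds) and zero-mean
participant offset curves sharing the regressor's length-scale with
their own kernel SD (~ Gamma(3, 5)). The noise SD σ is shared across
time points and carries a weak half-Cauchy(5) prior.

Because the model is linear-Gaussian given the kernel hyperparameters,
no black-box approximate inference is needed: each participant's trials
reduce to per-time GLS estimates with known Gaussian error; the
hyperparameter marginal likelihood has a closed form (latent curves
integrated out); hyperparameters are set by penalized
marginal-likelihood maximization (Nelder–Mead warm start, then BFGS);
and the posterior over group curves conditional on the fitted
hyperparameters is an exact Gaussian, from which ≥ 4000 draws supply the
HPDI bands. This conditional-posterior approach understates
hyperparameter uncertainty relative to a full posterior, which is the
usual trade-off of empirical-Bayes GP regression; the null calibration
below shows the resulting decision rule remains conservative.

Inference on a regressor proceeds by flagging time points whose HPDI
(99.9% at planning; 99.95% at outcome, compensating for the two
classifier training times tested there) excludes zero, then keeping only
runs of ≥ 3 contiguous flagged points. On null simulations the full rule
flags ≤ 1% of time points (it is in fact strongly conservative, near 0%),
and a Gaussian-bump effect curve is recovered with correlation > 0.8 at
moderate noise. Rank-deficient designs fail loudly, naming the collinear
columns.

`build_design()` constructs the phase designs with one row per
(trial, arm), since sequenceness is computed against each arm's
transition matrix: planning = {trial type, path type, chosen,
trial type × path type, trial number}; outcome (learning trials only) =
{chosen, path type, outcome, |PE|, outcome × |PE|, trial number}, with
|PE| recomputed from the fitted model by replaying the learning rule.
Binary regressors are mean-centered, continuous ones z-scored (a
`standardize = "center"` flag gives plain centering), and interactions
are products of centered parents, re-centered.

The data are decimated (default factor 4, 100 → 25 Hz) before fitting;
at ~150 time points per trial the exact linear algebra is comfortable
without inducing-point approximations. Problem sizes used in the
package's own validation: 8 participants × 15–20 trials × 40–50 time
points, chosen to make the 100-simulation null calibration cheap while
keeping the per-fit posterior exact.

## Power–reactivation coupling

`fit_power_glm()` regresses per-trial band power on mean-centered trial
regressors independently at each time point (OLS). Coefficients are
standardized by dividing each regressor's coefficient series by its
*variance* across time — implemented literally as stated, with an `"sd"`
option, since dividing by a variance is unusual enough to flag.
Group-level inference offers three levels: `group_mean_test()`
(trial-averaged coefficients against zero, Bonferroni over regions),
`temporal_cluster_permutation()` (1D cluster mass with participant sign
flipping; family-wise error verified ≤ 0.05 on null simulations), and
`autoregressive_coupling()` (signal at t predicted from its five
preceding samples plus the covariate at t, pooled across trials per
participant; group t test on the coupling coefficient, FDR across
multiple tests via `ar_coupling_suite()`). Whole-brain 4D clustering
and beamforming are out of scope; this module consumes region-level
power series, real or synthetic.

## Synthetic data

`stimulus_patterns()` draws one unit-norm spatial pattern per state
(272 channels by default; random high-dimensional vectors are
near-orthogonal, mimicking distinguishable evoked field maps) and a
Gaussian temporal response kernel (peak 200 ms, SD 50 ms).
`generate_localizer()` presents each of the 14 stimuli ~64 times over
900 trials (balanced random order): pattern × kernel × snr + unit
Gaussian sensor noise. `generate_task_epochs()` adds to noise epochs
optional isolated reactivations (one state's pattern pulsed at given or
random times, resolvable per trial to the chosen/unchosen terminal) and
replay events (a path's patterns pulsed in forward or reverse order at a
fixed inter-state lag, 10-ms pulse SD). `generate_power_series()` makes
per-trial power linear in reactivation strength inside a coupling
window, with clipping at zero that never binds at the default baseline,
keeping the generative model linear for recovery checks.

The noise model is iid Gaussian across channels and samples with an
optional AR(1) temporal option for stress-testing cluster inference.
What this deliberately does *not* emulate: spatially correlated sensor
noise, 1/f spectra, eye or cardiac artifacts, co-registration error, or
any biophysical forward model. Passing tests on these data show the
estimators are correct and calibrated under their own assumptions — they
do not show that real recordings satisfy those assumptions.

All generators are pure functions of (configuration, seed): they save
and restore the session RNG state, and identical seeds give identical
output.

## Orchestration

`run_pipeline(run_config(...))` chains the stages on a shared state,
refusing to run a stage whose upstream artifacts are missing (the error
names the stage to run first) and stamping the report with a content
hash of the config; reruns with the same config are numerically
identical. The defaults are deliberately small (4 participants,
16 trials, 32 channels) so a full chain finishes in minutes; study-scale
analyses call the stage functions directly. The package's interface is
its functions plus `scripts/acceptance.R`; no shell entry point is
shipped.

## Known limitations

* `alpha_minus` recovery is noise-limited at 120 trials (see above);
  studies needing tight individual asymmetry estimates would need more
  trials or stronger outcome contingencies.
* The lag-resolution of windowed sequenceness is coarse: the classifier
  embedding (±50 ms) and pulse width smear injected lags by about one
  10-ms step, so a 40-ms injection may peak at 50 ms.
* HLGPR hyperparameters are point estimates; HPDI bands condition on
  them.
* The per-option-score softmax and the literal divide-by-variance
  standardization are faithful readings of ambiguous descriptions; both
  are isolated behind flags so either reading can be tested.
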