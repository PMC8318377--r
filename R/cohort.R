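#' Simulate a cohort of participants from the learning model
#'
#' Generates a shared trial schedule and shock-probability walks (the same
#' pattern for every participant, as in the task design), draws
#' per-participant generating parameters, and simulates each participant's
#' choices. Defaults emulate the study conditions: 120 trials with 28%
#' generalization trials, learning rates spread over (0.1, 0.9), moderate
#' inverse temperature, and generalization weights spread evenly over
#' [0, 1] so that individual differences in model-based inference are
#' represented.
#'
#' @param n_participants Number of participants (default 28).
#' @param n_trials Trials per participant (default 120).
#' @param prop_generalization Proportion of generalization trials
#'   (default 0.28).
#' @param seed Integer seed.
#' @param beta_mean Mean inverse temperature on the log scale's natural
#'   value (default 5).
#' @param variant Generating variant, as in \code{\link{fit_hierarchical}}.
#' @return A list with \code{datasets} (list of \code{behavior_dataset}),
#'   \code{true_params} (data frame of generating parameters),
#'   \code{schedule} and \code{walks}.
#' @export
simulate_cohort <- function(n_participants = 28L, n_trials = 120L,
                            prop_generalization = 0.28, seed = 1L,
                            beta_mean = 5, variant = "asym_G") {
  spec <- variant_spec(variant)
  schedule <- generate_trial_schedule(n_trials, prop_generalization,
                                      seed = child_seed(seed, 1L))
  walks <- generate_shock_walk(n_trials, seed = child_seed(seed, 2L))
  pars <- with_seed(child_seed(seed, 3L), {
    ap <- stats::runif(n_participants, 0.1, 0.9)
    am <- if ("alpha" %in% spec$names) ap else stats::runif(n_participants, 0.1, 0.9)
    beta <- exp(stats::rnorm(n_participants, log(beta_mean), 0.3))
    G <- if ("G" %in% spec$names) {
      sample(seq(0.02, 0.98, length.out = n_participants))
    } else rep(0, n_participants)
    data.frame(id = seq_len(n_participants), alpha_plus = ap,
               alpha_minus = am, beta = beta, G = G)
  })
  datasets <- lapply(seq_len(n_participants), function(i) {
    p <- model_params(alpha_plus = pars$alpha_plus[i],
                      alpha_minus = pars$alpha_minus[i],
                      beta_softmax = pars$beta[i], G = pars$G[i],
                      asymmetric = TRUE, generalization = TRUE)
    simulate_choices(p, schedule, walks, seed = child_seed(seed, 100L + i),
                     id = i)
  })
  list(datasets = datasets, true_params = pars,
       schedule = schedule, walks = walks)
}
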