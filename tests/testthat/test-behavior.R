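test_that("value updates follow the asymmetric prediction-error rule", {
  p <- model_params(alpha_plus = 0.2, alpha_minus = 0.5)
  v <- c(V_M = 0.5, V_N = 0.5)
  # unexpected shock: delta = +0.5, alpha_plus applies
  v1 <- update_value(v, "M", 1, p)
  expect_equal(v1[["V_M"]], 0.6)
  expect_equal(v1[["V_N"]], 0.5)
  # better than expected: delta = -0.8, alpha_minus applies
  v2 <- update_value(c(V_M = 0.8, V_N = 0.5), "M", 0, p)
  expect_equal(v2[["V_M"]], 0.4)
  # delta = 0 leaves the value unchanged
  v3 <- update_value(c(V_M = 1, V_N = 0.5), "M", 1, p)
  expect_equal(v3[["V_M"]], 1)
  expect_error(update_value(v, "M", NA, p), "outcome")
})

test_that("values stay in [0, 1] under any in-bounds parameters", {
  set.seed(11)
  for (rep in 1:50) {
    p <- model_params(alpha_plus = runif(1), alpha_minus = runif(1),
                      beta_softmax = runif(1, 0, 20), G = runif(1))
    v <- c(V_M = runif(1), V_N = runif(1))
    for (k in 1:30) {
      v <- update_value(v, sample(c("M", "N"), 1), rbinom(1, 1, 0.5), p)
      expect_true(all(v >= 0 & v <= 1))
    }
  }
})

test_that("choice probabilities implement the G-scaled softmax", {
  p <- model_params(beta_softmax = 4, G = 0.5)
  # equal values: indifference
  expect_equal(choice_probability(c(V_M = 0.3, V_N = 0.3), "learning", p),
               0.5)
  # G = 0 collapses generalization-trial values to 0.5
  p0 <- model_params(beta_softmax = 10, G = 0, generalization = FALSE)
  expect_equal(
    choice_probability(c(V_M = 0.9, V_N = 0.1), "generalization", p0), 0.5)
  # hand arithmetic: V_M = 0.9, V_N = 0.5, G = 0.5 on a generalization
  # trial shrinks to (0.7, 0.5); safety values (0.3, 0.5); each option's
  # score exp(b*u)/(exp(b*u)+exp(b*(1-u))), then renormalized
  b <- 4
  u <- 1 - c(0.7, 0.5)
  s <- exp(b * u) / (exp(b * u) + exp(b * (1 - u)))
  expect_equal(
    choice_probability(c(V_M = 0.9, V_N = 0.5), "generalization",
                       model_params(beta_softmax = 4, G = 0.5)),
    s[1] / (s[1] + s[2]))
  # monotone decreasing in the chosen option's shock value
  pm <- vapply(seq(0, 1, by = 0.1), function(vm)
    choice_probability(c(V_M = vm, V_N = 0.5), "learning", p), numeric(1))
  expect_true(all(diff(pm) < 0))
})

test_that("simulated choices respect the no-update rule and noise limits", {
  sched <- generate_trial_schedule(400, 0.3, seed = 3)
  walks <- generate_shock_walk(400, seed = 3)
  # beta = 0: uniform choice
  d0 <- simulate_choices(model_params(beta_softmax = 0), sched, walks,
                         seed = 4)
  expect_lt(abs(mean(d0$chosen_terminal == "M") - 0.5),
            3 * sqrt(0.25 / 400))
  # values never change across a generalization trial
  d <- simulate_choices(model_params(), sched, walks, seed = 5)
  gen <- which(d$trial_type == "generalization")
  gen <- gen[gen < nrow(d)]
  expect_equal(d$v_M[gen + 1], d$v_M[gen])
  expect_equal(d$v_N[gen + 1], d$v_N[gen])
  expect_true(all(is.na(d$outcome[gen])))
  expect_true(all(d$outcome[d$trial_type == "learning"] %in% c(0, 1)))
  # deterministic given seed
  expect_identical(d, simulate_choices(model_params(), sched, walks,
                                       seed = 5))
  expect_error(simulate_choices(model_params(), sched,
                                generate_shock_walk(10, seed = 1)),
               "same number of trials")
})

test_that("a decisive learner with stationary walks picks the safer arm", {
  sched <- generate_trial_schedule(300, 0.2, seed = 6)
  walks <- generate_shock_walk(300, step_sd = 0, start = c(0.15, 0.85),
                               seed = 6)
  d <- simulate_choices(model_params(beta_softmax = 20, G = 1,
                                     alpha_plus = 0.3, alpha_minus = 0.3),
                        sched, walks, seed = 7)
  late <- d[d$trial > 100, ]
  expect_gt(mean(late$chosen_terminal == "M"), 0.95)
})

test_that("log-likelihood matches an independent trial-loop recomputation", {
  for (s in 1:5) {
    p <- model_params(alpha_plus = runif(1, 0.1, 0.9),
                      alpha_minus = runif(1, 0.1, 0.9),
                      beta_softmax = runif(1, 0.5, 10), G = runif(1))
    d <- small_behavior(n = 60, seed = s, params = p)
    expect_equal(log_likelihood(d, p), bf_loglik(d, p), tolerance = 1e-12)
  }
  # beta = 0 forces P = 0.5 on every trial
  d <- small_behavior(n = 80, seed = 1)
  expect_equal(sum(log_likelihood(d, model_params(beta_softmax = 0))),
               -80 * log(2), tolerance = 1e-10)
})

test_that("generating parameters outscore perturbed ones on average", {
  set.seed(21)
  gen <- model_params(alpha_plus = 0.3, alpha_minus = 0.6,
                      beta_softmax = 6, G = 0.7)
  diffs <- vapply(1:40, function(s) {
    d <- small_behavior(n = 120, seed = s, params = gen)
    pert <- model_params(
      alpha_plus = min(1, max(0, 0.3 + runif(1, -0.25, 0.25))),
      alpha_minus = min(1, max(0, 0.6 + runif(1, -0.25, 0.25))),
      beta_softmax = max(0, 6 + runif(1, -4, 4)),
      G = min(1, max(0, 0.7 + runif(1, -0.4, 0.4))))
    sum(log_likelihood(d, gen)) - sum(log_likelihood(d, pert))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("the consistency index scores terminal repetition after learning", {
  base <- small_behavior(n = 20, seed = 2)
  d <- base
  d$trial_type <- rep(c("learning", "generalization"), 10)
  d$chosen_terminal <- rep("M", 20)
  d$outcome <- ifelse(d$trial_type == "learning", 1, NA)
  expect_equal(consistency_index(d), 1)
  d$chosen_terminal <- rep(c("M", "N"), 10)
  expect_equal(consistency_index(d), 0)
  # invariant to relabelling M and N
  d2 <- small_behavior(n = 80, seed = 3)
  flip <- d2
  flip$chosen_terminal <- c(M = "N", N = "M")[d2$chosen_terminal]
  expect_equal(consistency_index(flip), consistency_index(d2))
  d3 <- base[base$trial_type == "learning", ]
  expect_error(consistency_index(d3), "generalization")
})

test_that("behavior tables round-trip through TSV", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  d <- small_behavior(n = 30, seed = 9)
  write_behavior_tsv(d, tmp)
  d2 <- read_behavior_tsv(tmp)
  expect_equal(d2$chosen_terminal, d$chosen_terminal)
  expect_equal(d2$outcome, d$outcome)
  expect_equal(sum(log_likelihood(d2, model_params())),
               sum(log_likelihood(d, model_params())))
})
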