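make_null_data <- function(P = 6, ntr = 10, Tn = 30, sd = 0.5, seed = 1) {
  set.seed(seed)
  X1 <- rnorm(P * ntr)
  y <- matrix(rnorm(P * ntr * Tn, sd = sd), P * ntr, Tn)
  hlgpr_data(y, cbind(x1 = X1), rep(seq_len(P), each = ntr),
             times = seq(0, by = 0.04, length.out = Tn))
}

test_that("HPDI matches an independent narrowest-interval computation", {
  set.seed(2)
  draws <- c(rnorm(400), rexp(200))
  for (lvl in c(0.9, 0.999, 0.9995)) {
    got <- avreplay:::hpdi(draws, lvl)
    expect_equal(got, bf_hpdi(draws, lvl), tolerance = 1e-12)
  }
})

test_that("a zero series with intercept-only yields a null posterior", {
  Tn <- 20
  d <- hlgpr_data(matrix(0, 12, Tn), NULL, rep(1:4, each = 3),
                  times = seq(0, by = 0.04, length.out = Tn))
  fit <- fit_hlgpr(d, n_draws = 1500, seed = 3)
  expect_lt(max(abs(fit$mean)), 1e-3)
  bands <- hpdi_curves(fit, 0.999)
  expect_true(all(bands$lower <= 0 & bands$upper >= 0))
  expect_equal(nrow(hpdi_significance(fit, 0.999)), 0)
  # HPDI bounds bracket the posterior mean everywhere
  expect_true(all(bands$lower <= fit$mean & fit$mean <= bands$upper))
})

test_that("rank-deficient designs fail naming the collinear regressor", {
  y <- matrix(rnorm(80), 8, 10)
  X <- cbind(a = rep(1:2, 4), b = rep(1:2, 4) * 2)
  expect_error(hlgpr_data(y, X, rep(1:2, each = 4)), "collinear.*b")
})

test_that("data preconditions are enforced", {
  d <- make_null_data(P = 1, ntr = 8)
  expect_error(fit_hlgpr(d), "2 participants")
  d2 <- make_null_data(Tn = 5)
  expect_error(fit_hlgpr(d2), "10 time points")
})

test_that("a known bump effect is recovered and flagged", {
  set.seed(5)
  P <- 6; ntr <- 15; Tn <- 40
  times <- seq(0, by = 0.04, length.out = Tn)
  bump <- 0.6 * exp(-(times - 0.8)^2 / (2 * 0.12^2))
  X1 <- rnorm(P * ntr)
  y <- X1 %o% bump + matrix(rnorm(P * ntr * Tn, sd = 0.5), P * ntr, Tn)
  d <- hlgpr_data(y, cbind(x1 = X1), rep(seq_len(P), each = ntr),
                  times = times)
  fit <- fit_hlgpr(d, n_draws = 3000, seed = 6)
  expect_gt(cor(fit$mean[, "x1"], bump), 0.8)
  sig <- hpdi_significance(fit, 0.999)
  sig <- sig[sig$regressor == "x1", ]
  expect_gt(nrow(sig), 0)
  # the flagged window brackets the true bump peak
  expect_true(any(sig$t_start <= 0.8 & sig$t_end >= 0.8))
})

test_that("scaling the data scales the posterior curves linearly", {
  set.seed(7)
  P <- 5; ntr <- 12; Tn <- 25
  times <- seq(0, by = 0.04, length.out = Tn)
  eff <- 0.5 * sin(times * 3)
  X1 <- rnorm(P * ntr)
  y <- X1 %o% eff + matrix(rnorm(P * ntr * Tn, sd = 0.1), P * ntr, Tn)
  pid <- rep(seq_len(P), each = ntr)
  f1 <- fit_hlgpr(hlgpr_data(y, cbind(x1 = X1), pid, times = times),
                  n_draws = 500, seed = 8)
  f3 <- fit_hlgpr(hlgpr_data(3 * y, cbind(x1 = X1), pid, times = times),
                  n_draws = 500, seed = 8)
  expect_equal(f3$mean[, "x1"], 3 * f1$mean[, "x1"], tolerance = 0.1)
})

test_that("duplicating a participant leaves the group posterior stable", {
  set.seed(9)
  ntr <- 15; Tn <- 25
  times <- seq(0, by = 0.04, length.out = Tn)
  eff <- 0.4 * cos(times * 2)
  X1 <- rnorm(2 * ntr)
  y <- X1 %o% eff + matrix(rnorm(2 * ntr * Tn, sd = 0.2), 2 * ntr, Tn)
  pid2 <- rep(1:2, each = ntr)
  f2 <- fit_hlgpr(hlgpr_data(y, cbind(x1 = X1), pid2, times = times),
                  n_draws = 500, seed = 10)
  y4 <- rbind(y, y)
  pid4 <- c(pid2, pid2 + 2)
  f4 <- fit_hlgpr(hlgpr_data(y4, cbind(x1 = X1[c(seq_along(X1),
                                                 seq_along(X1))]),
                             pid4, times = times),
                  n_draws = 500, seed = 10)
  expect_gt(cor(f2$mean[, "x1"], f4$mean[, "x1"]), 0.95)
})

test_that("cluster rule discards isolated flagged points", {
  # construct a posterior object with two isolated significant points
  Tn <- 12
  draws <- array(rnorm(2000 * Tn * 1, sd = 0.1), c(2000, Tn, 1),
                 dimnames = list(NULL, NULL, "x1"))
  draws[, 4, 1] <- abs(draws[, 4, 1]) + 1   # all positive, isolated
  draws[, 9, 1] <- abs(draws[, 9, 1]) + 1   # all positive, isolated
  post <- structure(
    list(times = seq_len(Tn) * 0.04, regressors = "x1",
         mean = matrix(colMeans(draws[, , 1]), Tn, 1,
                       dimnames = list(NULL, "x1")),
         draws = draws, n_draws = 2000),
    class = "gp_posterior")
  expect_equal(nrow(hpdi_significance(post, 0.999, min_cluster = 3)), 0)
  # but a single all-positive point is flagged at min_cluster = 1
  expect_equal(nrow(hpdi_significance(post, 0.999, min_cluster = 1)), 2)
  expect_error(hpdi_significance(post, 1.5), "probability")
})

test_that("designs are centred with product interactions and model PEs", {
  p <- model_params(alpha_plus = 0.4, alpha_minus = 0.3, beta_softmax = 5,
                    G = 0.6)
  beh <- small_behavior(n = 50, seed = 11, params = p)
  des <- build_design("planning", beh, p)
  expect_equal(unname(colMeans(des$X)), rep(0, ncol(des$X)),
               tolerance = 1e-10)
  prod_tt_pt <- des$X[, "trial_type"] * des$X[, "path_type"]
  expect_equal(des$X[, "trial_type_x_path_type"],
               prod_tt_pt - mean(prod_tt_pt))
  expect_equal(nrow(des$X), 4 * nrow(beh))
  out <- build_design("outcome", beh, p)
  expect_equal(unname(colMeans(out$X)), rep(0, ncol(out$X)),
               tolerance = 1e-10)
  learn <- which(beh$trial_type == "learning")
  expect_equal(nrow(out$X), 4 * length(learn))
  # |PE| equals a brute-force replay of the learning rule
  traj <- value_trajectory(beh, p)
  v <- c(0.5, 0.5)
  pe_bf <- rep(NA_real_, nrow(beh))
  for (t in seq_len(nrow(beh))) {
    if (beh$trial_type[t] == "learning") {
      i <- if (beh$chosen_terminal[t] == "M") 1 else 2
      pe_bf[t] <- beh$outcome[t] - v[i]
      a <- if (pe_bf[t] > 0) p$alpha_plus else p$alpha_minus
      v[i] <- v[i] + a * pe_bf[t]
    }
  }
  expect_equal(traj$pe, pe_bf, tolerance = 1e-12)
  raw_abs_pe <- abs(pe_bf[out$trial])
  expect_gt(cor(out$X[, "abs_pe"], raw_abs_pe), 0.999)
})
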