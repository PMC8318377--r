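tm <- build_task_map()
T_all <- transition_matrix(tm)
T_arm <- transition_matrix(tm, "learning_M")

test_that("sequenceness equals the brute-force pairwise-correlation loop", {
  set.seed(12)
  for (rep in 1:5) {
    react <- matrix(runif(80 * 14), 80, 14)
    got <- compute_sequenceness(react, T_all)
    want <- bf_sequenceness(react, T_all)
    expect_equal(got$forward, want$forward, tolerance = 1e-10)
    expect_equal(got$backward, want$backward, tolerance = 1e-10)
    expect_equal(got$difference, want$difference, tolerance = 1e-10)
  }
})

test_that("a deterministic forward chain peaks at its construction lag", {
  d0 <- 4
  n_t <- 120
  react <- matrix(0, n_t, 14)
  path <- match(tm$arms$learning_M, tm$states)
  # repeat the sequence B -> F -> J -> M with inter-state lag d0
  starts <- seq(1, n_t - 3 * d0 - 1, by = 3 * d0 + 8)
  for (s0 in starts) {
    for (k in seq_along(path)) react[s0 + (k - 1) * d0, path[k]] <- 1
  }
  res <- compute_sequenceness(react, T_arm, max_lag = 10)
  expect_equal(which.max(res$difference), d0)
  expect_gt(res$difference[d0], 0)
  # time reversal flips the sign exactly, at every lag
  rev_res <- compute_sequenceness(react[n_t:1, ], T_arm, max_lag = 10)
  expect_equal(rev_res$difference, -res$difference, tolerance = 1e-12)
  expect_equal(rev_res$forward, res$backward, tolerance = 1e-12)
})

test_that("antisymmetry under time reversal holds for arbitrary input", {
  set.seed(13)
  react <- matrix(rnorm(60 * 14), 60, 14)
  a <- compute_sequenceness(react, T_all, max_lag = 15)
  b <- compute_sequenceness(react[60:1, ], T_all, max_lag = 15)
  expect_equal(b$difference, -a$difference, tolerance = 1e-12)
})

test_that("consistent state relabelling leaves sequenceness unchanged", {
  set.seed(14)
  react <- matrix(runif(50 * 14), 50, 14)
  perm <- sample(14)
  a <- compute_sequenceness(react, T_all, max_lag = 8)
  b <- compute_sequenceness(react[, perm], T_all[perm, perm], max_lag = 8)
  expect_equal(b$difference, a$difference, tolerance = 1e-12)
})

test_that("iid noise gives zero-centred difference and zero-variance flags", {
  set.seed(15)
  diffs <- replicate(300, {
    react <- matrix(rnorm(40 * 14), 40, 14)
    mean(compute_sequenceness(react, T_all, max_lag = 5)$difference)
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(300))
  # a constant state series is flagged and contributes zero
  react <- matrix(rnorm(40 * 14), 40, 14)
  react[, 2] <- 0.5   # state B, on a transition
  res <- compute_sequenceness(react, T_all, max_lag = 5)
  expect_true(2 %in% attr(res, "zero_variance_states"))
  expect_true(all(is.finite(res$difference)))
  expect_error(compute_sequenceness(matrix(1, 10, 14), T_all, max_lag = 20),
               "max_lag")
})

test_that("a full-trial window reproduces whole-trial sequenceness", {
  set.seed(16)
  react <- matrix(runif(50 * 14), 50, 14)
  whole <- compute_sequenceness(react, T_all, max_lag = 12)
  sw <- sliding_window_sequenceness(react, T_all, window = 50,
                                    max_lag = 12)
  expect_equal(nrow(sw$difference), 1)
  expect_equal(as.numeric(sw$difference), whole$difference,
               tolerance = 1e-12)
  expect_error(sliding_window_sequenceness(react, T_all, window = 10,
                                           max_lag = 20),
               "max_lag")
})

test_that("collapse_lags reduces the lag axis as documented", {
  set.seed(17)
  react <- matrix(runif(90 * 14), 90, 14)
  sw <- sliding_window_sequenceness(react, T_all, window = 30, step = 5,
                                    max_lag = 10)
  expect_equal(collapse_lags(sw, 4), sw$difference[, 4])
  expect_equal(collapse_lags(sw, 2:6),
               rowMeans(sw$difference[, 2:6]))
  ma <- collapse_lags(sw, 1:10, method = "max_abs")
  expect_equal(abs(ma), apply(abs(sw$difference), 1, max))
  expect_error(collapse_lags(sw, integer(0)), "non-empty")
  expect_error(collapse_lags(sw, 15), "outside")
})

test_that("mean arm sequenceness averages per-arm differences", {
  set.seed(18)
  react <- matrix(runif(60 * 14), 60, 14)
  m <- mean_arm_sequenceness(react, tm, max_lag = 6)
  per <- sapply(names(tm$arms), function(a)
    compute_sequenceness(react, transition_matrix(tm, a),
                         max_lag = 6)$difference)
  expect_equal(m$difference, rowMeans(per), tolerance = 1e-12)
})
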