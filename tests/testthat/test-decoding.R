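test_that("binary grids decode a strong pattern and are reproducible", {
  pat <- shared_patterns()
  loc <- generate_localizer(pat, n_trials = 280, snr = 4, seed = 21)
  g1 <- train_binary_grid(loc, c("M", "N"),
                          train_times = c(0.1, 0.2, 0.3), seed = 22)
  # accuracy peaks at the response latency (0.2 s)
  expect_equal(which.max(g1$cv_accuracy), 2)
  expect_gt(max(g1$cv_accuracy), 0.85)
  # determinism: same seed, identical hyperparameters and weights
  g2 <- train_binary_grid(loc, c("M", "N"),
                          train_times = c(0.1, 0.2, 0.3), seed = 22)
  expect_identical(g1$models[[2]]$lambda, g2$models[[2]]$lambda)
  expect_identical(g1$models[[2]]$beta, g2$models[[2]]$beta)
  expect_error(train_binary_grid(loc, c("M", "Z")), "both states")
})

test_that("label-shuffled training stays within the chance band", {
  pat <- shared_patterns()
  loc <- generate_localizer(pat, n_trials = 280, snr = 2, seed = 23)
  shuffled <- sensor_epochs(loc$data, loc$times, loc$sfreq,
                            with_seed(24, sample(loc$labels)))
  g <- train_binary_grid(shuffled, c("M", "N"), train_times = 0.2,
                         seed = 25)
  n_pair <- sum(shuffled$labels %in% c("M", "N"))
  expect_lt(abs(g$cv_accuracy - 0.5), 3 * sqrt(0.25 / n_pair) + 0.05)
})

test_that("temporal generalization localizes injected terminal patterns", {
  pat <- shared_patterns()
  loc <- generate_localizer(pat, n_trials = 280, snr = 3, seed = 26)
  grid <- train_binary_grid(loc, c("M", "N"), train_times = 0.2, seed = 27)
  beh <- small_behavior(n = 16, seed = 28)
  # chosen terminal's pattern injected at 2 s
  ep <- generate_task_epochs(
    beh, pat,
    react = reactivation_spec("chosen_terminal", times = 2,
                              pulse_width = 0.02),
    snr = 3, seed = 29, duration = 3)
  am <- temporal_generalization(grid, ep, beh$chosen_terminal,
                                task_times = c(1, 2, 2.5))
  expect_gt(am[1, "2000"], am[1, "1000"] + 0.2)
  expect_gt(am[1, "2000"], 0.8)
  # unchosen pattern injected: accuracy flips below chance
  ep_u <- generate_task_epochs(
    beh, pat,
    react = reactivation_spec("unchosen_terminal", times = 2,
                              pulse_width = 0.02),
    snr = 3, seed = 30, duration = 3)
  am_u <- temporal_generalization(grid, ep_u, beh$chosen_terminal,
                                  task_times = c(1, 2))
  expect_lt(am_u[1, "2000"], 0.2)
  # probabilistic predictions live in [0, 1] and match the accuracy cells
  pr <- attr(am, "prob_chosen")
  expect_true(all(pr >= 0 & pr <= 1))
  # channel mismatch is refused
  bad <- sensor_epochs(ep$data[, 1:10, , drop = FALSE], ep$times, 100)
  expect_error(temporal_generalization(grid, bad, beh$chosen_terminal),
               "channel")
})

test_that("state classifiers decode held-out data well above chance", {
  pat <- shared_patterns()
  clf <- shared_state_classifiers()
  expect_gte(clf$n_components, 30)
  expect_lte(clf$n_components, 60)
  held_out <- generate_localizer(pat, n_trials = 280, snr = 2, seed = 45)
  pr <- predict(clf, held_out)
  expect_gt(mean(pr$label == held_out$labels), 5 / 14)
  expect_equal(rowSums(pr$prob), rep(1, 280), tolerance = 1e-9)
  # embedding edge handling
  expect_error(train_state_classifiers(shared_localizer(),
                                       train_time = 0.02, seed = 1),
               "epoch edge")
})

test_that("classifier pipelines are invariant to channel permutation", {
  pat <- shared_patterns()
  loc <- generate_localizer(pat, n_trials = 280, snr = 2, seed = 31)
  set.seed(32)
  perm <- sample(64)
  loc_p <- sensor_epochs(loc$data[, perm, , drop = FALSE], loc$times,
                         loc$sfreq, loc$labels)
  g <- train_binary_grid(loc, c("M", "N"), train_times = 0.2, seed = 33)
  g_p <- train_binary_grid(loc_p, c("M", "N"), train_times = 0.2,
                           seed = 33)
  test <- generate_localizer(pat, n_trials = 140, snr = 2, seed = 34)
  keep <- test$labels %in% c("M", "N")
  te <- sensor_epochs(test$data[keep, , , drop = FALSE], test$times, 100,
                      test$labels[keep])
  te_p <- sensor_epochs(test$data[keep, perm, , drop = FALSE], test$times,
                        100, test$labels[keep])
  a <- temporal_generalization(g, te, te$labels, task_times = 0.2)
  a_p <- temporal_generalization(g_p, te_p, te_p$labels, task_times = 0.2)
  expect_equal(as.numeric(a), as.numeric(a_p), tolerance = 1e-6)
})

test_that("reactivation time courses trim the embedding and find pulses", {
  pat <- shared_patterns()
  clf <- shared_state_classifiers()
  beh <- small_behavior(n = 4, seed = 35)
  ep <- generate_task_epochs(
    beh, pat,
    react = reactivation_spec("G", times = c(1.5), amplitude = 2,
                              pulse_width = 0.02),
    snr = 2, seed = 36, duration = 6)
  rm <- reactivation_timecourse(clf, ep, trial = 1)
  expect_equal(dim(rm), c(590, 14))
  expect_true(all(rm >= 0 & rm <= 1))
  expect_equal(rowSums(rm), rep(1, 590), tolerance = 1e-9)
  # at the pulse, the injected state dominates
  t_idx <- which.min(abs(attr(rm, "times") - 1.5))
  expect_equal(colnames(rm)[which.max(rm[t_idx, ])], "G")
})

test_that("reactivation strength reduces masked cells as documented", {
  pr <- array(runif(5 * 3 * 4), c(5, 3, 4))
  mask1 <- matrix(FALSE, 3, 4); mask1[2, 3] <- TRUE
  expect_equal(reactivation_strength(pr, mask1), pr[, 2, 3])
  uni <- array(0.5, c(5, 3, 4))
  maskA <- matrix(TRUE, 3, 4)
  expect_equal(reactivation_strength(uni, maskA), rep(0.5, 5))
  expect_error(reactivation_strength(pr, matrix(FALSE, 3, 4)),
               "at least one cell")
})

test_that("2D cluster permutation flags coherent effects, rejects bad input", {
  set.seed(37)
  P <- 10
  null_maps <- lapply(1:P, function(i) matrix(rnorm(12 * 12, 0.5, 0.05),
                                              12, 12))
  expect_error(cluster_test_map(null_maps[1:5], 0.5), "8 participants")
  expect_error(cluster_test_map(null_maps, 0.5, n_perm = 50), "100")
  same <- lapply(1:P, function(i) matrix(0.5, 6, 6))
  expect_error(cluster_test_map(same, 0.5, n_perm = 200), "degenerate")
  # injected coherent blob is detected
  blob_maps <- lapply(null_maps, function(m) {
    m[4:7, 4:7] <- m[4:7, 4:7] + 0.12
    m
  })
  res <- cluster_test_map(blob_maps, 0.5, n_perm = 500, seed = 38)
  expect_true(any(res$clusters$p < 0.05 & res$clusters$sign > 0))
  big <- res$clusters[which.max(res$clusters$mass), ]
  expect_gte(big$n_cells, 8)
  # correlation comparator: covariate-driven effect detected
  g_vals <- seq(0, 1, length.out = P)
  corr_maps <- lapply(1:P, function(i) {
    m <- matrix(rnorm(12 * 12, 0, 0.05), 12, 12)
    m[2:5, 2:5] <- m[2:5, 2:5] + 0.25 * g_vals[i]
    m
  })
  res_c <- cluster_test_map(corr_maps, g_vals, n_perm = 500, seed = 39)
  expect_true(any(res_c$clusters$p < 0.05))
})

test_that("2D cluster permutation controls family-wise error on null maps", {
  fp <- 0L
  for (s in 1:200) {
    set.seed(4000 + s)
    maps <- lapply(1:10, function(i) matrix(rnorm(12 * 12, 0.5, 0.05),
                                            12, 12))
    res <- cluster_test_map(maps, 0.5, n_perm = 200, seed = 4000 + s)
    if (nrow(res$clusters) > 0 && any(res$clusters$p < 0.05)) fp <- fp + 1L
  }
  expect_lte(fp / 200, 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})
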