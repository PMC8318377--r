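test_that("stimulus patterns are unit norm and distinguishable", {
  pat <- stimulus_patterns(n_channels = 272, seed = 2)
  expect_equal(dim(pat$patterns), c(14, 272))
  expect_equal(sqrt(rowSums(pat$patterns^2)), rep(1, 14),
               tolerance = 1e-12, ignore_attr = TRUE)
  cs <- tcrossprod(pat$patterns)
  expect_lt(max(abs(cs[lower.tri(cs)])), 0.9)
})

test_that("localizer presentation counts are balanced", {
  pat <- shared_patterns()
  loc <- generate_localizer(pat, n_trials = 900, snr = 1, seed = 3)
  counts <- table(loc$labels)
  expect_length(counts, 14)
  expect_true(all(counts >= 64 - 2 & counts <= 64 + 2))
  expect_equal(dim(loc$data), c(900, 64, 81))
  # purity: same seed, identical epochs; RNG state untouched
  set.seed(99); before <- .Random.seed
  loc2 <- generate_localizer(pat, n_trials = 900, snr = 1, seed = 3)
  expect_identical(.Random.seed, before)
  expect_identical(loc$data, loc2$data)
  expect_error(generate_localizer(pat, snr = -1), "non-negative")
})

test_that("replay injection places patterns at the specified times", {
  pat <- shared_patterns()
  beh <- small_behavior(n = 2, seed = 4)
  rsp <- replay_spec("learning_M", lag = 0.04, onset = 1.5, amplitude = 5,
                     pulse_width = 0.01)
  ep <- generate_task_epochs(beh, pat, replay = rsp, snr = 1, seed = 5)
  # project each sample onto each path state's pattern; peak must sit at
  # onset + (k-1) * lag, in path order
  path <- c("B", "F", "J", "M")
  for (k in seq_along(path)) {
    proj <- as.numeric(pat$patterns[path[k], ] %*% ep$data[1, , ])
    expect_equal(ep$times[which.max(proj)], 1.5 + (k - 1) * 0.04,
                 tolerance = 0.011)
  }
  # reverse direction: same times, reversed state order
  rsp_r <- replay_spec("learning_M", lag = 0.04, direction = "reverse",
                       onset = 1.5, amplitude = 5, pulse_width = 0.01)
  ep_r <- generate_task_epochs(beh, pat, replay = rsp_r, snr = 1, seed = 5)
  for (k in seq_along(path)) {
    proj <- as.numeric(pat$patterns[path[k], ] %*% ep_r$data[1, , ])
    expect_equal(ep_r$times[which.max(proj)],
                 1.5 + (length(path) - k) * 0.04, tolerance = 0.011)
  }
  # zero amplitude: statistically indistinguishable from noise
  rsp_0 <- replay_spec("learning_M", onset = 1.5, amplitude = 0)
  ep_0 <- generate_task_epochs(beh, pat, replay = rsp_0, snr = 1, seed = 6)
  expect_lt(abs(mean(ep_0$data)), 0.005)
  expect_lt(abs(sd(ep_0$data) - 1), 0.01)
  # specs outside the epoch are refused
  expect_error(
    generate_task_epochs(beh, pat,
                         replay = replay_spec("learning_M", onset = 5.95),
                         seed = 7),
    "epoch bounds")
  expect_error(replay_spec("learning_M", lag = 0.5), "200 ms")
  expect_error(replay_spec("no_such_arm"), "unknown arm")
})

test_that("reactivation injection resolves chosen and unchosen terminals", {
  pat <- shared_patterns()
  beh <- small_behavior(n = 6, seed = 8)
  ep <- generate_task_epochs(
    beh, pat,
    react = reactivation_spec("unchosen_terminal", times = 1,
                              amplitude = 5, pulse_width = 0.01),
    snr = 1, seed = 9, duration = 2.8)
  t_idx <- which.min(abs(ep$times - 1))
  for (tr in 1:6) {
    un <- c(M = "N", N = "M")[[beh$chosen_terminal[tr]]]
    ch <- beh$chosen_terminal[tr]
    proj_un <- as.numeric(pat$patterns[un, ] %*% ep$data[tr, , t_idx])
    proj_ch <- as.numeric(pat$patterns[ch, ] %*% ep$data[tr, , t_idx])
    expect_gt(proj_un, proj_ch + 1)
  }
})

test_that("power series are linear in strength and clipped at zero", {
  strength <- c(0, 0.5, 1)
  pw <- generate_power_series(strength, beta = 2, noise_sd = 0, seed = 1,
                              n_time = 10)
  expect_equal(unclass(pw), 5 + 2 * outer(strength, rep(1, 10)),
               ignore_attr = TRUE)
  pw_neg <- generate_power_series(-10, beta = 2, noise_sd = 0, seed = 1,
                                  n_time = 4)
  expect_true(all(pw_neg == 0))
  expect_error(generate_power_series(1, beta = 1, noise_sd = -1),
               "non-negative")
})

test_that("AR(1) noise option induces temporal autocorrelation", {
  pat <- stimulus_patterns(n_channels = 8, seed = 10)
  beh <- small_behavior(n = 3, seed = 11)
  ep <- generate_task_epochs(beh, pat, snr = 0, seed = 12, duration = 2,
                             ar = 0.8)
  x <- ep$data[1, 1, ]
  r1 <- cor(x[-1], x[-length(x)])
  expect_gt(r1, 0.5)
  ep0 <- generate_task_epochs(beh, pat, snr = 0, seed = 12, duration = 2)
  x0 <- ep0$data[1, 1, ]
  expect_lt(abs(cor(x0[-1], x0[-length(x0)])), 0.3)
})
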