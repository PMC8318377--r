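#' Configuration for a full analysis run
#'
#' Collects every knob of the simulate -> fit-behavior -> decode ->
#' sequenceness -> hlgpr -> couple chain in one serializable list. A run
#' is reproducible from its config alone: every randomized step derives
#' its seed from \code{seed}, and the run report records a content hash of
#' the config.
#'
#' @param seed Master integer seed.
#' @param stages Character vector of stages to run, in order.
#' @param n_participants Participants simulated for the neural stages.
#' @param n_trials Task trials per participant.
#' @param n_channels Simulated sensor channels.
#' @param localizer_trials Localizer trials per participant.
#' @param snr Injection amplitude relative to unit sensor noise.
#' @param replay_lag Injected inter-state lag in seconds.
#' @param replay_onset Injected replay onset range (seconds).
#' @param replay_direction \code{"forward"} or \code{"reverse"}.
#' @param train_time Classifier training time (seconds after stimulus
#'   onset).
#' @param window Sequenceness window length in samples.
#' @param window_step Sliding-window step in samples.
#' @param max_lag Maximum sequenceness lag in samples.
#' @param coupling_beta Ground-truth power-reactivation coupling.
#' @param hlgpr_draws Posterior draws for the HLGPR stage.
#' @param variant Behavior-model variant to fit.
#' @return A \code{run_config} list.
#' @export
run_config <- function(seed = 1L,
                       stages = c("simulate", "fit_behavior", "decode",
                                  "sequenceness", "hlgpr", "couple"),
                       n_participants = 4L, n_trials = 16L,
                       n_channels = 32L, localizer_trials = 280L,
                       snr = 2, replay_lag = 0.04,
                       replay_onset = c(1.4, 1.8),
                       replay_direction = "forward", train_time = 0.2,
                       window = 40L, window_step = 5L, max_lag = 20L,
                       coupling_beta = 0.5, hlgpr_draws = 2000L,
                       variant = "asym_G") {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

require_stage <- function(state, key, stage, upstream) {
  if (is.null(state[[key]])) {
    stop("stage '", stage, "' requires artifacts from stage '", upstream,
         "'; run it first")
  }
}

#' Run the analysis pipeline on synthetic data
#'
#' Executes the requested stages in order on a shared state: simulate a
#' cohort with injected replay and coupled power series; fit the behavior
#' model hierarchically; train state classifiers and decode reactivation;
#' compute sliding-window sequenceness; fit the hierarchical latent GP
#' regression on the collapsed sequenceness series; and test
#' power-reactivation coupling. Returns a run report comparing recovered
#' quantities with the simulation's ground truth where available.
#'
#' @param config A \code{\link{run_config}}.
#' @return An object of class \code{run_report}: per-stage summaries plus
#'   the config and its content hash.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  state <- new.env(parent = emptyenv())
  report <- list(config = config, config_hash = config_hash(config),
                 stages = list())
  for (stage in config$stages) {
    report$stages[[stage]] <- switch(
      stage,
      simulate = stage_simulate(state, config),
      fit_behavior = stage_fit_behavior(state, config),
      decode = stage_decode(state, config),
      sequenceness = stage_sequenceness(state, config),
      hlgpr = stage_hlgpr(state, config),
      couple = stage_couple(state, config),
      stop("unknown stage: ", stage)
    )
  }
  class(report) <- "run_report"
  report
}

stage_simulate <- function(state, cfg) {
  coh <- simulate_cohort(cfg$n_participants, cfg$n_trials,
                         seed = child_seed(cfg$seed, 1L))
  pat <- stimulus_patterns(n_channels = cfg$n_channels,
                           seed = child_seed(cfg$seed, 2L))
  rsp <- replay_spec("learning_M", lag = cfg$replay_lag,
                     direction = cfg$replay_direction,
                     onset = cfg$replay_onset, amplitude = 1,
                     n_events = 3L)
  state$cohort <- coh
  state$patterns <- pat
  state$replay <- rsp
  state$localizers <- lapply(seq_len(cfg$n_participants), function(i)
    generate_localizer(pat, cfg$localizer_trials, snr = cfg$snr,
                       seed = child_seed(cfg$seed, 10L + i)))
  state$task_epochs <- lapply(seq_len(cfg$n_participants), function(i)
    generate_task_epochs(coh$datasets[[i]], pat, replay = rsp,
                         snr = cfg$snr,
                         seed = child_seed(cfg$seed, 40L + i)))
  list(n_participants = cfg$n_participants, n_trials = cfg$n_trials,
       replay = list(direction = cfg$replay_direction,
                     lag_ms = cfg$replay_lag * 1000,
                     onset_s = cfg$replay_onset))
}

stage_fit_behavior <- function(state, cfg) {
  require_stage(state, "cohort", "fit_behavior", "simulate")
  fit <- fit_hierarchical(state$cohort$datasets, cfg$variant,
                          seed = child_seed(cfg$seed, 3L))
  state$behavior_fit <- fit
  est <- coef_table(fit)
  truth <- state$cohort$true_params
  list(variant = fit$variant, waic = fit$waic,
       converged = fit$converged,
       recovery_r = c(G = stats::cor(truth$G, est$G),
                      alpha_plus = stats::cor(truth$alpha_plus,
                                              est$alpha_plus),
                      alpha_minus = stats::cor(truth$alpha_minus,
                                               est$alpha_minus)),
       consistency = vapply(state$cohort$datasets, consistency_index,
                            numeric(1)))
}

stage_decode <- function(state, cfg) {
  require_stage(state, "localizers", "decode", "simulate")
  state$classifiers <- lapply(seq_along(state$localizers), function(i)
    train_state_classifiers(state$localizers[[i]], cfg$train_time,
                            seed = child_seed(cfg$seed, 70L + i)))
  state$reactivations <- lapply(seq_along(state$classifiers), function(i) {
    ep <- state$task_epochs[[i]]
    lapply(seq_len(n_trials(ep)), function(tr)
      reactivation_timecourse(state$classifiers[[i]], ep, tr))
  })
  list(cv_accuracy = vapply(state$classifiers, `[[`, numeric(1),
                            "cv_accuracy"),
       n_timepoints = nrow(state$reactivations[[1L]][[1L]]))
}

stage_sequenceness <- function(state, cfg) {
  require_stage(state, "reactivations", "sequenceness", "decode")
  Tm <- transition_matrix(build_task_map(), "learning_M")
  state$seq <- lapply(state$reactivations, function(trials)
    lapply(trials, function(rm)
      sliding_window_sequenceness(rm, Tm, window = cfg$window,
                                  step = cfg$window_step,
                                  max_lag = cfg$max_lag)))
  # mean difference map across participants and trials
  D <- Reduce(`+`, lapply(state$seq, function(trials)
    Reduce(`+`, lapply(trials, `[[`, "difference")) / length(trials))) /
    length(state$seq)
  pk <- which(D == max(D), arr.ind = TRUE)
  sw <- state$seq[[1L]][[1L]]
  state$seq_template <- sw
  list(peak_lag_ms = sw$lags[pk[2L]] * 10,
       peak_time_s = (sw$centers[pk[1L]] + 5) / 100,
       peak_difference = max(D), mean_difference = mean(D))
}

stage_hlgpr <- function(state, cfg) {
  require_stage(state, "seq", "hlgpr", "sequenceness")
  require_stage(state, "behavior_fit", "hlgpr", "fit_behavior")
  lag_band <- 3:5  # 30-50 ms, bracketing the injected lag
  y_list <- list(); X_list <- list(); pid <- character()
  for (i in seq_along(state$seq)) {
    beh <- state$cohort$datasets[[i]]
    est <- state$behavior_fit$participants[[i]]$mean
    pars <- model_params(est[["alpha_plus"]], est[["alpha_minus"]],
                         est[["beta"]], est[["G"]])
    des <- build_design("planning", beh, pars)
    keep <- des$arm == "learning_M"
    series <- t(vapply(state$seq[[i]], collapse_lags, lag_range = lag_band,
                       numeric(nrow(state$seq[[i]][[1L]]$difference))))
    y_list[[i]] <- series[des$trial[keep], , drop = FALSE]
    X_list[[i]] <- des$X[keep, c("trial_type", "chosen"), drop = FALSE]
    pid <- c(pid, rep(as.character(i), sum(keep)))
  }
  y <- do.call(rbind, y_list)
  X <- do.call(rbind, X_list)
  centers <- state$seq_template$centers
  dat <- hlgpr_data(y, X, pid, times = (centers + 5) / 100, decimate = 4L)
  fit <- fit_hlgpr(dat, n_draws = cfg$hlgpr_draws,
                   seed = child_seed(cfg$seed, 5L))
  state$hlgpr_fit <- fit
  sig <- hpdi_significance(fit, 0.999)
  icpt <- sig[sig$regressor == "(intercept)", , drop = FALSE]
  list(significant_clusters = sig,
       replay_detected = nrow(icpt) > 0 && any(icpt$sign > 0),
       converged = fit$diagnostics$convergence == 0L)
}

stage_couple <- function(state, cfg) {
  require_stage(state, "reactivations", "couple", "decode")
  strengths <- lapply(state$reactivations, function(trials)
    vapply(trials, function(rm) mean(rm[, "M"]), numeric(1)))
  betas <- lapply(seq_along(strengths), function(i) {
    pw <- generate_power_series(strengths[[i]], beta = cfg$coupling_beta,
                                noise_sd = 0.3,
                                seed = child_seed(cfg$seed, 90L + i))
    fit_power_glm(pw, cbind(reactivation = strengths[[i]]),
                  standardize = "none")
  })
  grp <- group_mean_test(list(simulated_region = betas),
                         regressor = "reactivation")
  series <- lapply(betas, function(b) b$beta[, "reactivation"])
  perm <- temporal_cluster_permutation(series, n_perm = 500L,
                                       seed = child_seed(cfg$seed, 6L))
  list(true_beta = cfg$coupling_beta,
       mean_recovered_beta = grp$mean, group_t = grp$t,
       group_p_bonferroni = grp$p_bonferroni,
       n_significant_clusters = sum(perm$clusters$p < 0.05))
}

#' @export
print.run_report <- function(x, ...) {
  cat("avreplay run report (config", x$config_hash, ")\n")
  for (nm in names(x$stages)) {
    cat("\n--", nm, "--\n")
    utils::str(x$stages[[nm]], max.level = 2, give.attr = FALSE)
  }
  invisible(x)
}

#' Write a run report to JSON
#' @param report A \code{run_report}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(config_hash = report$config_hash,
         config = unclass(report$config), stages = report$stages),
    path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
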