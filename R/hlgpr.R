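# Hierarchical latent Gaussian-process regression (HLGPR).
#
# Observed series y (one row per trial, one column per time point) are
# modelled as y[j, t] ~ N(sum_r X[j, r] * beta[p(j), r](t), sigma^2) with
# time-varying regression weights beta[i, r](t) = g_r(t) + d_{i,r}(t):
# a group-level curve g_r with a constant-mean squared-exponential GP
# prior, plus participant-level offset curves d_{i,r} with a zero-mean SE
# GP prior. The length-scale is shared between the group and participant
# level of a regressor but varies across regressors.
#
# Conditional on the kernel hyperparameters the model is linear-Gaussian,
# so the latent curves are integrated analytically: each participant's
# trials reduce to per-time GLS estimates with known Gaussian error, the
# marginal likelihood of the hyperparameters has a closed form, and the
# posterior over group curves is an exact Gaussian. Hyperparameters are
# set by maximizing the marginal likelihood penalized by their priors
# (Gamma(3,1) on length-scales, Gamma(3,5) on kernel SDs, N(0,5) on the
# constant means, half-Cauchy(5) on the noise SD); posterior draws for
# HPDI bands come from the conditional Gaussian.

se_kernel <- function(times, ell, sd_k, jitter = 1e-8) {
  d <- outer(times, times, "-")
  sd_k^2 * exp(-d^2 / (2 * ell^2)) + diag(jitter, length(times))
}

block_diag <- function(blocks) {
  sizes <- vapply(blocks, nrow, integer(1))
  out <- matrix(0, sum(sizes), sum(sizes))
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    out[idx, idx] <- b
    at <- at + nrow(b)
  }
  out
}

#' Assemble data for hierarchical latent GP regression
#'
#' @param y Numeric matrix, observations x time (e.g. collapsed
#'   sequenceness per trial/path).
#' @param X Numeric matrix of per-observation regressors (constant within
#'   trial), or NULL for an intercept-only model. An intercept column is
#'   added automatically. Columns must be named.
#' @param participant Vector of participant identifiers, one per row of
#'   \code{y}.
#' @param times Time axis in seconds (default: 25 Hz grid, matching
#'   sequenceness decimated by 4 from 100 Hz).
#' @param decimate Integer factor by which to decimate \code{y} (and
#'   \code{times}) by keeping every k-th sample (default 1 = none; use 4
#'   to go from 100 Hz to 25 Hz).
#' @return An object of class \code{hlgpr_data}.
#' @export
hlgpr_data <- function(y, X = NULL, participant, times = NULL,
                       decimate = 1L) {
  y <- as.matrix(y)
  n_obs <- nrow(y)
  stopifnot(length(participant) == n_obs)
  if (decimate > 1L) {
    keep <- seq(1L, ncol(y), by = decimate)
    y <- y[, keep, drop = FALSE]
    if (!is.null(times)) times <- times[keep]
  }
  if (is.null(times)) times <- seq(0, by = 0.04, length.out = ncol(y))
  stopifnot(length(times) == ncol(y))
  if (is.null(X)) {
    X <- matrix(numeric(0), n_obs, 0L)
  } else {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  Xf <- cbind(`(intercept)` = 1, X)
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    bad <- colnames(Xf)[qrX$pivot[(qrX$rank + 1L):ncol(Xf)]]
    stop("design matrix is rank deficient; collinear regressor(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(y = y, X = Xf, participant = as.character(participant),
                 times = times, decimate = as.integer(decimate)),
            class = "hlgpr_data")
}

# per-participant sufficient statistics for the reduced model
hlgpr_stats <- function(data) {
  ids <- unique(data$participant)
  R <- ncol(data$X); Tn <- ncol(data$y)
  lapply(ids, function(id) {
    rows <- which(data$participant == id)
    Xi <- data$X[rows, , drop = FALSE]
    Yi <- data$y[rows, , drop = FALSE]
    XtX <- crossprod(Xi)
    M <- tryCatch(solve(XtX), error = function(e) {
      stop("participant ", id, " has too few observations to identify ",
           "all regressors")
    })
    Zhat <- M %*% crossprod(Xi, Yi)            # R x T GLS estimates
    RSS <- sum((Yi - Xi %*% Zhat)^2)
    list(id = id, n = length(rows), M = M,
         logdet_M = determinant(M, logarithm = TRUE)$modulus[1L],
         z = as.vector(t(Zhat)), RSS = RSS,
         kronM = kronecker(M, diag(Tn)))
  })
}

unpack_theta <- function(theta, R) {
  list(
    ell   = exp(theta[seq_len(R)]),
    sg    = exp(theta[R + seq_len(R)]),
    sp    = exp(theta[2L * R + seq_len(R)]),
    mu    = theta[3L * R + seq_len(R)],
    sigma = exp(theta[4L * R + 1L])
  )
}

# negative penalized log marginal likelihood of the hyperparameters
hlgpr_nll <- function(theta, stats, times, R) {
  hp <- unpack_theta(theta, R)
  Tn <- length(times)
  RT <- R * Tn
  Kg <- block_diag(lapply(seq_len(R), function(r)
    se_kernel(times, hp$ell[r], hp$sg[r])))
  Kf <- block_diag(lapply(seq_len(R), function(r)
    se_kernel(times, hp$ell[r], hp$sp[r])))
  m0 <- rep(hp$mu, each = Tn)
  cg <- tryCatch(chol(Kg), error = function(e) NULL)
  if (is.null(cg)) return(1e10)
  Kg_inv <- chol2inv(cg)
  logdet_Kg <- 2 * sum(log(diag(cg)))
  Lam <- Kg_inv
  h <- Kg_inv %*% m0
  cc <- sum(m0 * (Kg_inv %*% m0))
  log_sum <- 0
  logD <- 0
  s2 <- hp$sigma^2
  for (st in stats) {
    S <- s2 * st$kronM + Kf
    cs <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(cs)) return(1e10)
    S_inv <- chol2inv(cs)
    Lam <- Lam + S_inv
    Sz <- S_inv %*% st$z
    h <- h + Sz
    cc <- cc + sum(st$z * Sz)
    log_sum <- log_sum - sum(log(diag(cs))) - (RT / 2) * log(2 * pi)
    logD <- logD - (st$n * Tn / 2) * log(2 * pi * s2) - st$RSS / (2 * s2) +
      (RT / 2) * log(2 * pi) +
      0.5 * (RT * log(s2) + Tn * st$logdet_M)
  }
  cl <- tryCatch(chol(Lam), error = function(e) NULL)
  if (is.null(cl)) return(1e10)
  logdet_Lam <- 2 * sum(log(diag(cl)))
  hLh <- sum(backsolve(cl, h, transpose = TRUE)^2)
  log_int <- log_sum - 0.5 * logdet_Kg - 0.5 * logdet_Lam -
    0.5 * (cc - hLh)
  # hyperpriors (with log-scale Jacobians for the transformed parameters)
  lp <- sum(stats::dgamma(hp$ell, 3, 1, log = TRUE) + log(hp$ell)) +
    sum(stats::dgamma(hp$sg, 3, 5, log = TRUE) + log(hp$sg)) +
    sum(stats::dgamma(hp$sp, 3, 5, log = TRUE) + log(hp$sp)) +
    sum(stats::dnorm(hp$mu, 0, 5, log = TRUE)) +
    log(2) + stats::dcauchy(hp$sigma, 0, 5, log = TRUE) + log(hp$sigma)
  out <- -(logD + log_int + lp)
  if (!is.finite(out)) 1e10 else out
}

#' Fit the hierarchical latent GP regression
#'
#' Estimates kernel hyperparameters by penalized marginal-likelihood
#' maximization (the latent group and participant curves are integrated
#' out analytically), then draws from the exact Gaussian posterior over
#' the group-level weight curves conditional on those hyperparameters.
#'
#' @param data An \code{\link{hlgpr_data}} object.
#' @param n_draws Posterior draws for HPDI computation (default 4000).
#' @param optimize Optimize hyperparameters (default TRUE); if FALSE the
#'   initial values are used as-is.
#' @param maxit Maximum optimizer iterations (default 200).
#' @param seed Integer seed for the posterior draws.
#' @param init Optional named list overriding initial hyperparameters
#'   (\code{ell}, \code{sg}, \code{sp}, \code{mu}, \code{sigma}).
#' @return An object of class \code{gp_posterior}: \code{mean} (time x
#'   regressor posterior mean curves), \code{draws} (draws x time x
#'   regressor array), \code{times}, \code{regressors}, fitted
#'   \code{hyperparams}, per-participant offset curve estimates
#'   (\code{participant_offsets}) and optimizer diagnostics. A failure of
#'   the optimizer to converge is recorded in
#'   \code{$diagnostics$convergence} and raised as a warning, never
#'   silent.
#' @export
fit_hlgpr <- function(data, n_draws = 4000L, optimize = TRUE, maxit = 200L,
                      seed = 1L, init = NULL) {
  stopifnot(inherits(data, "hlgpr_data"))
  ids <- unique(data$participant)
  if (length(ids) < 2L) stop("need at least 2 participants")
  if (ncol(data$y) < 10L) stop("need at least 10 time points")
  R <- ncol(data$X); Tn <- ncol(data$y)
  times <- data$times
  stats_l <- hlgpr_stats(data)

  span <- max(times) - min(times)
  init_full <- list(ell = rep(max(span / 4, 0.1), R),
                    sg = rep(stats::sd(data$y) + 1e-3, R),
                    sp = rep(0.5 * stats::sd(data$y) + 1e-3, R),
                    mu = rep(0, R),
                    sigma = stats::sd(data$y) + 1e-3)
  if (!is.null(init)) init_full[names(init)] <- init
  theta0 <- c(log(init_full$ell), log(init_full$sg), log(init_full$sp),
              init_full$mu, log(init_full$sigma))

  diag_info <- list(convergence = 0L, message = "not optimized")
  if (optimize) {
    opt <- stats::optim(theta0, hlgpr_nll, stats = stats_l, times = times,
                        R = R, method = "Nelder-Mead",
                        control = list(maxit = maxit * 10L))
    opt <- stats::optim(opt$par, hlgpr_nll, stats = stats_l, times = times,
                        R = R, method = "BFGS",
                        control = list(maxit = maxit))
    theta <- opt$par
    diag_info <- list(convergence = opt$convergence,
                      message = if (opt$convergence == 0L) "converged"
                                else "optimizer did not converge",
                      nll = opt$value)
    if (opt$convergence != 0L) {
      warning("HLGPR hyperparameter optimization did not converge ",
              "(code ", opt$convergence, ")")
    }
  } else {
    theta <- theta0
  }
  hp <- unpack_theta(theta, R)

  # exact Gaussian posterior over the group curves at the fitted
  # hyperparameters
  Kg <- block_diag(lapply(seq_len(R), function(r)
    se_kernel(times, hp$ell[r], hp$sg[r])))
  Kf <- block_diag(lapply(seq_len(R), function(r)
    se_kernel(times, hp$ell[r], hp$sp[r])))
  m0 <- rep(hp$mu, each = Tn)
  Kg_inv <- chol2inv(chol(Kg))
  Lam <- Kg_inv
  h <- Kg_inv %*% m0
  S_invs <- vector("list", length(stats_l))
  for (i in seq_along(stats_l)) {
    S <- hp$sigma^2 * stats_l[[i]]$kronM + Kf
    S_invs[[i]] <- chol2inv(chol(S))
    Lam <- Lam + S_invs[[i]]
    h <- h + S_invs[[i]] %*% stats_l[[i]]$z
  }
  cl <- chol(Lam)
  post_cov <- chol2inv(cl)
  post_mean <- as.vector(post_cov %*% h)

  draws_flat <- with_seed(seed, rmvnorm_chol(n_draws, post_mean, post_cov))
  draws <- array(NA_real_, c(n_draws, Tn, R),
                 dimnames = list(NULL, NULL, colnames(data$X)))
  for (r in seq_len(R)) {
    draws[, , r] <- draws_flat[, (r - 1L) * Tn + seq_len(Tn)]
  }
  mean_mat <- matrix(post_mean, Tn, R,
                     dimnames = list(NULL, colnames(data$X)))

  # participant offset curves: posterior mean of d_i given the group mean
  offsets <- lapply(seq_along(stats_l), function(i) {
    resid <- stats_l[[i]]$z - post_mean
    d <- as.vector(Kf %*% (S_invs[[i]] %*% resid))
    matrix(d, Tn, R, dimnames = list(NULL, colnames(data$X)))
  })
  names(offsets) <- vapply(stats_l, `[[`, character(1), "id")

  structure(
    list(times = times, regressors = colnames(data$X), mean = mean_mat,
         draws = draws, participant_offsets = offsets,
         hyperparams = hp, diagnostics = diag_info, n_draws = n_draws),
    class = "gp_posterior"
  )
}

#' @export
print.gp_posterior <- function(x, ...) {
  cat("HLGPR posterior:", length(x$regressors), "regressor(s) x",
      length(x$times), "time points,", x$n_draws, "draws\n")
  cat("  regressors:", paste(x$regressors, collapse = ", "), "\n")
  invisible(x)
}

#' HPDI curves of a fitted HLGPR posterior
#'
#' @param post A \code{gp_posterior}.
#' @param level HPDI probability level (e.g. 0.999).
#' @return A list with per-regressor matrices \code{lower}, \code{upper}
#'   (time x regressor) at the requested level.
#' @export
hpdi_curves <- function(post, level = 0.999) {
  Tn <- length(post$times); R <- length(post$regressors)
  lower <- upper <- matrix(NA_real_, Tn, R,
                           dimnames = list(NULL, post$regressors))
  for (r in seq_len(R)) for (t in seq_len(Tn)) {
    b <- hpdi(post$draws[, t, r], level)
    lower[t, r] <- b[1L]; upper[t, r] <- b[2L]
  }
  list(lower = lower, upper = upper)
}

#' Significant time clusters from HPDI exclusion of zero
#'
#' Flags time points whose HPDI excludes zero and groups them into runs of
#' temporal contiguity; runs shorter than \code{min_cluster} points are
#' discarded (the decision rule: HPDI excludes zero at three or more
#' contiguous time points). The 0.999 level is the planning-phase default;
#' 0.9995 compensates for testing two classifier training times at
#' outcome.
#'
#' @param post A \code{gp_posterior}.
#' @param level HPDI level in (0.5, 1); typically 0.999 or 0.9995.
#' @param min_cluster Minimum run length (default 3).
#' @return A data frame with one row per significant cluster: regressor,
#'   start/end time indices and times, sign.
#' @export
hpdi_significance <- function(post, level = 0.999, min_cluster = 3L) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0.5 ||
      level >= 1) {
    stop("level must be a probability in (0.5, 1)")
  }
  bands <- hpdi_curves(post, level)
  out <- data.frame(regressor = character(), start = integer(),
                    end = integer(), t_start = numeric(),
                    t_end = numeric(), sign = numeric())
  for (r in seq_along(post$regressors)) {
    excl <- bands$lower[, r] > 0 | bands$upper[, r] < 0
    for (run in true_runs(excl)) {
      if (length(run) >= min_cluster) {
        out <- rbind(out, data.frame(
          regressor = post$regressors[r],
          start = run[1L], end = run[length(run)],
          t_start = post$times[run[1L]],
          t_end = post$times[run[length(run)]],
          sign = sign(mean(post$mean[run, r]))
        ))
      }
    }
  }
  out
}

#' Build the HLGPR design matrix for a task phase
#'
#' One row per arm per trial (sequenceness is computed against every
#' arm's transition matrix). For the planning phase: trial type
#' (generalization = 1), path type (generalization arm = 1), whether the
#' path was chosen, the trial type x path type interaction, and trial
#' number. For the outcome phase (learning trials only): whether the path
#' was chosen, path type, outcome, absolute prediction error from the
#' fitted model, outcome x |PE| interaction, and trial number. Binary
#' regressors are mean-centered and continuous regressors z-scored by
#' default (\code{standardize = "zscore"}); interactions are products of
#' the centered parents, re-centered so every column has mean zero.
#'
#' @param phase \code{"planning"} or \code{"outcome"}.
#' @param behavior A \code{behavior_dataset}.
#' @param params Fitted \code{\link{model_params}} (used to recompute the
#'   model-implied prediction errors).
#' @param task_map Task map for arm metadata.
#' @param standardize \code{"zscore"} (continuous regressors z-scored) or
#'   \code{"center"} (mean-centered only).
#' @return A list with \code{X} (the centered design matrix), \code{trial}
#'   (trial index per row) and \code{arm} (arm name per row).
#' @export
build_design <- function(phase = c("planning", "outcome"), behavior, params,
                         task_map = build_task_map(),
                         standardize = c("zscore", "center")) {
  phase <- match.arg(phase)
  standardize <- match.arg(standardize)
  traj <- value_trajectory(behavior, params)
  ctr <- function(x) x - mean(x)
  std <- function(x) {
    if (standardize == "zscore" && stats::sd(x) > 0) {
      (x - mean(x)) / stats::sd(x)
    } else ctr(x)
  }
  # sequenceness is computed per arm transition matrix, for all arms on
  # every trial, so the design has one row per (trial, arm)
  arms <- names(task_map$arms)
  rows_for <- function(trials) {
    data.frame(
      trial = rep(trials, each = length(arms)),
      arm = rep(arms, times = length(trials))
    )
  }
  if (phase == "planning") {
    rows <- rows_for(seq_len(nrow(behavior)))
    trial_type <- ctr(as.numeric(
      behavior$trial_type[rows$trial] == "generalization"))
    path_type <- ctr(as.numeric(
      task_map$arm_type[rows$arm] == "generalization"))
    chosen <- ctr(as.numeric(
      behavior$chosen_arm[rows$trial] == rows$arm))
    X <- cbind(trial_type = trial_type, path_type = path_type,
               chosen = chosen,
               trial_type_x_path_type = trial_type * path_type,
               trial_number = std(behavior$trial[rows$trial]))
  } else {
    learn <- which(behavior$trial_type == "learning")
    if (any(is.na(traj$pe[learn]))) {
      stop("missing prediction error on learning trial(s)")
    }
    rows <- rows_for(learn)
    chosen <- ctr(as.numeric(behavior$chosen_arm[rows$trial] == rows$arm))
    path_type <- ctr(as.numeric(
      task_map$arm_type[rows$arm] == "generalization"))
    outcome <- ctr(behavior$outcome[rows$trial])
    abs_pe <- std(abs(traj$pe[rows$trial]))
    X <- cbind(chosen = chosen, path_type = path_type, outcome = outcome,
               abs_pe = abs_pe, outcome_x_abs_pe = ctr(outcome * abs_pe),
               trial_number = std(behavior$trial[rows$trial]))
  }
  list(X = X, trial = rows$trial, arm = rows$arm)
}
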