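# Coupling of band-limited power (e.g. hippocampal theta) to reactivation
# and replay: per-participant time-resolved GLMs across trials, group
# tests with Bonferroni correction over regions, temporal cluster
# permutation by participant-level sign flipping, and autoregressive
# within-trial coupling models.

#' Time-resolved GLM predicting power from trial regressors
#'
#' Fits an ordinary least squares model independently at each time point,
#' predicting per-trial power from mean-centered trial-level regressors
#' (reactivation strength, and at outcome additionally outcome, |PE| and
#' their interaction) plus an intercept. Coefficients are standardized by
#' dividing each regressor's coefficient time series by its variance
#' across time (the \code{"sd"} option divides by the standard deviation
#' instead; \code{"none"} disables standardization).
#'
#' @param power Trials x time matrix of band power (a
#'   \code{\link{generate_power_series}} object or any numeric matrix).
#' @param regressors Trials x k matrix of trial-level regressors; centered
#'   internally if any column mean is nonzero.
#' @param standardize \code{"variance"} (default), \code{"sd"} or
#'   \code{"none"}.
#' @return An object of class \code{beta_series}: \code{beta} (time x
#'   (1 + k), standardized), \code{raw} (unstandardized), regressor names.
#' @export
fit_power_glm <- function(power, regressors,
                          standardize = c("variance", "sd", "none")) {
  standardize <- match.arg(standardize)
  power <- unclass(as.matrix(power))
  n_tr <- nrow(power)
  if (n_tr < 10L) stop("need at least 10 trials")
  X <- as.matrix(regressors)
  if (ncol(X) > 0L) {
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    X <- sweep(X, 2L, colMeans(X))
  }
  Xf <- cbind(`(intercept)` = 1, X)
  if (qr(Xf)$rank < ncol(Xf)) stop("singular design matrix")
  # one OLS solve for all time points at once
  B <- solve(crossprod(Xf), crossprod(Xf, power))   # (1+k) x time
  raw <- t(B)
  beta <- raw
  if (standardize != "none") {
    for (j in seq_len(ncol(beta))) {
      s <- if (standardize == "variance") stats::var(raw[, j])
           else stats::sd(raw[, j])
      if (s > 0) beta[, j] <- raw[, j] / s
    }
  }
  structure(list(beta = beta, raw = raw, regressors = colnames(Xf),
                 standardize = standardize),
            class = "beta_series")
}

#' Group test of trial-averaged coupling coefficients
#'
#' Averages each participant's coefficient time series over time, then
#' tests the participant means against zero with a one-sample t test per
#' region, Bonferroni-correcting over the number of regions (two for left
#' and right hippocampus).
#'
#' @param region_betas Named list of regions; each element a list of
#'   per-participant \code{beta_series} (or time x regressor matrices).
#' @param regressor Column name or index of the coefficient of interest
#'   (default 2, the first non-intercept regressor).
#' @param use_raw Use unstandardized coefficients (default FALSE).
#' @return Data frame with one row per region: mean coefficient, t, df,
#'   raw p and Bonferroni-corrected p (factor = number of regions).
#' @export
group_mean_test <- function(region_betas, regressor = 2L, use_raw = FALSE) {
  if (inherits(region_betas, "beta_series") ||
      !is.list(region_betas[[1L]])) {
    region_betas <- list(region = region_betas)
  }
  n_regions <- length(region_betas)
  out <- lapply(names(region_betas), function(rg) {
    vals <- vapply(region_betas[[rg]], function(b) {
      m <- if (inherits(b, "beta_series")) {
        if (use_raw) b$raw else b$beta
      } else as.matrix(b)
      mean(m[, regressor])
    }, numeric(1))
    if (length(vals) < 3L) stop("need at least 3 participants")
    if (stats::sd(vals) == 0) {
      stop("zero variance across participants in region ", rg)
    }
    tt <- stats::t.test(vals)
    data.frame(region = rg, mean = mean(vals),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               p_bonferroni = min(1, n_regions * tt$p.value))
  })
  do.call(rbind, out)
}

# 1D cluster masses above a t threshold, by sign
runs_mass <- function(tvec, t_crit) {
  out <- list()
  for (sgn in c(1, -1)) {
    for (run in true_runs(sgn * tvec > t_crit)) {
      out[[length(out) + 1L]] <- list(sign = sgn,
                                      mass = sum(abs(tvec[run])),
                                      start = run[1L],
                                      end = run[length(run)])
    }
  }
  out
}

#' Temporal cluster permutation test on coefficient time series
#'
#' One-sample test of per-participant coefficient time series against
#' zero: pointwise t statistics are thresholded (two-sided p < 0.05 by
#' default), contiguous suprathreshold runs form clusters scored by mass
#' (summed |t|), and the null distribution of the maximum cluster mass is
#' built by randomly sign-flipping whole participants.
#'
#' @param betas List of per-participant numeric vectors (one coefficient
#'   time series each), or a participants x time matrix.
#' @param n_perm Number of sign-flip permutations (>= 100; default 5000).
#' @param threshold_p Pointwise two-sided cluster-forming threshold.
#' @param seed Integer seed.
#' @return A list with \code{t} (pointwise t series) and \code{clusters}
#'   (data frame: start, end, sign, mass, p).
#' @export
temporal_cluster_permutation <- function(betas, n_perm = 5000L,
                                         threshold_p = 0.05, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  B <- if (is.matrix(betas)) betas else do.call(rbind, betas)
  P <- nrow(B)
  if (P < 3L) stop("need at least 3 participants")
  df <- P - 1L
  t_crit <- stats::qt(1 - threshold_p / 2, df)
  SS <- colSums(B^2)
  t_of <- function(signs) {
    m <- colMeans(B * signs)
    v <- (SS - P * m^2) / df
    se <- sqrt(v / P)
    tv <- m / se
    tv[!is.finite(tv)] <- 0
    tv
  }
  t_obs <- t_of(rep(1, P))
  obs <- runs_mass(t_obs, t_crit)
  null_max <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    cl <- runs_mass(t_of(sample(c(-1, 1), P, replace = TRUE)), t_crit)
    if (length(cl) == 0L) 0 else max(vapply(cl, `[[`, numeric(1), "mass"))
  }, numeric(1)))
  clusters <- if (length(obs) == 0L) {
    data.frame(start = integer(), end = integer(), sign = numeric(),
               mass = numeric(), p = numeric())
  } else {
    do.call(rbind, lapply(obs, function(cl) {
      data.frame(start = cl$start, end = cl$end, sign = cl$sign,
                 mass = cl$mass,
                 p = (1 + sum(null_max >= cl$mass)) / (n_perm + 1))
    }))
  }
  list(t = t_obs, clusters = clusters)
}

#' Autoregressive within-trial coupling model
#'
#' For each participant, predicts the signal (power amplitude or phase) at
#' each time point from its five preceding time points plus the
#' corresponding covariate (state reactivation or sequenceness) value at
#' the same time point, pooling rows across trials. The per-participant
#' covariate (coupling) coefficients are then tested against zero with a
#' one-sample t test.
#'
#' @param signals List of per-participant trials x time matrices.
#' @param covariates List of per-participant trials x time matrices,
#'   matching \code{signals} in shape.
#' @param order Autoregressive order (default 5).
#' @return A list with \code{per_participant} (data frame of AR and
#'   coupling coefficients), \code{t}, \code{df}, \code{p} for the group
#'   test on the coupling coefficient.
#' @export
autoregressive_coupling <- function(signals, covariates, order = 5L) {
  stopifnot(length(signals) == length(covariates))
  coefs <- lapply(seq_along(signals), function(i) {
    S <- as.matrix(signals[[i]]); C <- as.matrix(covariates[[i]])
    stopifnot(all(dim(S) == dim(C)))
    Tn <- ncol(S)
    if (Tn <= order + 2L) stop("series length must exceed order + 2")
    if (stats::sd(S) == 0) stop("constant signal for participant ", i)
    idx <- (order + 1L):Tn
    y <- as.vector(S[, idx])
    lagX <- vapply(seq_len(order), function(l) as.vector(S[, idx - l]),
                   numeric(length(y)))
    colnames(lagX) <- paste0("ar", seq_len(order))
    X <- cbind(lagX, coupling = as.vector(C[, idx]))
    fit <- stats::lm(y ~ X)
    cf <- stats::coef(fit)
    names(cf) <- sub("^X", "", names(cf))
    cf
  })
  per <- as.data.frame(do.call(rbind, coefs))
  cp <- per$coupling
  tt <- stats::t.test(cp)
  list(per_participant = per, mean_coupling = mean(cp),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Run several AR coupling tests with FDR correction
#'
#' Convenience wrapper running \code{\link{autoregressive_coupling}} for a
#' named set of covariates (e.g. reactivation and sequenceness in several
#' frequency bands) and adjusting the group p-values for multiple
#' comparisons by false discovery rate.
#'
#' @param signals List of per-participant trials x time matrices.
#' @param covariate_sets Named list; each element a list of per-participant
#'   covariate matrices.
#' @param order Autoregressive order.
#' @return Data frame with one row per test: mean coupling, t, df, p and
#'   FDR-adjusted p.
#' @export
ar_coupling_suite <- function(signals, covariate_sets, order = 5L) {
  res <- lapply(covariate_sets, function(cv)
    autoregressive_coupling(signals, cv, order))
  out <- data.frame(
    test = names(covariate_sets),
    mean_coupling = vapply(res, `[[`, numeric(1), "mean_coupling"),
    t = vapply(res, `[[`, numeric(1), "t"),
    df = vapply(res, `[[`, numeric(1), "df"),
    p = vapply(res, `[[`, numeric(1), "p")
  )
  out$p_fdr <- stats::p.adjust(out$p, method = "fdr")
  rownames(out) <- NULL
  out
}
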