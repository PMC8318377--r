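#' Lag-resolved sequenceness from a reactivation matrix
#'
#' Quantifies evidence that states reactivate in an order consistent with
#' the task transition structure. For each lag d (in samples), the forward
#' statistic is the mean, over ordered state pairs (i, j) with a task
#' transition i -> j, of the Pearson correlation between state i's
#' reactivation time course shifted back by d samples and state j's
#' time course; the backward statistic uses the transposed transition
#' matrix. Their difference indexes the balance of forward versus reverse
#' replay (the subtraction cancels the shared autocorrelation, so neither
#' direction is interpreted alone).
#'
#' @param react Numeric matrix, time points x states (reactivation
#'   probabilities or evidence).
#' @param T_mat Binary transition matrix (states x states), e.g. from
#'   \code{\link{transition_matrix}}.
#' @param max_lag Maximum lag in samples (default 20, i.e. 200 ms at
#'   100 Hz).
#' @return A data frame with columns \code{lag}, \code{forward},
#'   \code{backward}, \code{difference}. A state time course with zero
#'   variance contributes correlation 0 to its pairs and is flagged via
#'   the \code{"zero_variance_states"} attribute.
#' @export
compute_sequenceness <- function(react, T_mat, max_lag = 20L) {
  react <- as.matrix(react)
  n_t <- nrow(react)
  if (n_t < max_lag + 2L) stop("need at least max_lag + 2 time points")
  if (ncol(react) != nrow(T_mat)) stop("state dimension mismatch")
  fwd_pairs <- which(T_mat == 1, arr.ind = TRUE)
  if (nrow(fwd_pairs) == 0L) stop("transition matrix has no transitions")
  zero_var <- logical(ncol(react))
  fwd <- bwd <- numeric(max_lag)
  for (d in seq_len(max_lag)) {
    past <- react[seq_len(n_t - d), , drop = FALSE]
    pres <- react[(d + 1L):n_t, , drop = FALSE]
    sd_past <- apply(past, 2L, stats::sd)
    sd_pres <- apply(pres, 2L, stats::sd)
    zero_var <- zero_var | sd_past == 0 | sd_pres == 0
    cc <- matrix(0, ncol(react), ncol(react))
    ok_i <- sd_past > 0; ok_j <- sd_pres > 0
    if (any(ok_i) && any(ok_j)) {
      cc[ok_i, ok_j] <- stats::cor(past[, ok_i, drop = FALSE],
                                   pres[, ok_j, drop = FALSE])
    }
    # forward: past state i predicts present state j along i -> j
    fwd[d] <- mean(cc[fwd_pairs])
    # backward: past state j predicts present state i (reverse traversal)
    bwd[d] <- mean(cc[fwd_pairs[, c(2L, 1L), drop = FALSE]])
  }
  out <- data.frame(lag = seq_len(max_lag), forward = fwd, backward = bwd,
                    difference = fwd - bwd)
  attr(out, "zero_variance_states") <- which(zero_var)
  class(out) <- c("sequenceness", "data.frame")
  out
}

#' Sliding-window sequenceness
#'
#' Applies \code{\link{compute_sequenceness}} within sliding windows
#' across a trial, indexing the result by window centre so that
#' fluctuations in replay evidence within the trial can be resolved.
#' Edges without a full window are omitted.
#'
#' @inheritParams compute_sequenceness
#' @param window Window length in samples (default 40, i.e. 400 ms at
#'   100 Hz). Must be at least \code{max_lag + 2}.
#' @param step Window step in samples (default 1).
#' @return An object of class \code{sliding_sequenceness}: a list with
#'   \code{forward}, \code{backward}, \code{difference} (matrices, window
#'   centre x lag), \code{centers} (sample indices of window centres,
#'   1-based), \code{window}, \code{lags}.
#' @export
sliding_window_sequenceness <- function(react, T_mat, window = 40L,
                                        step = 1L, max_lag = 20L) {
  react <- as.matrix(react)
  if (window < max_lag + 2L) stop("window must be at least max_lag + 2 samples")
  n_t <- nrow(react)
  if (n_t < window) stop("trial shorter than one window")
  starts <- seq.int(1L, n_t - window + 1L, by = step)
  centers <- starts + (window - 1L) / 2
  k <- length(starts)
  fwd <- bwd <- dif <- matrix(NA_real_, k, max_lag)
  for (w in seq_len(k)) {
    seg <- react[starts[w]:(starts[w] + window - 1L), , drop = FALSE]
    s <- compute_sequenceness(seg, T_mat, max_lag)
    fwd[w, ] <- s$forward; bwd[w, ] <- s$backward; dif[w, ] <- s$difference
  }
  structure(
    list(forward = fwd, backward = bwd, difference = dif,
         centers = centers, window = window, lags = seq_len(max_lag)),
    class = "sliding_sequenceness"
  )
}

#' Collapse the lag dimension of a sliding sequenceness result
#'
#' Reduces the window-centre x lag difference matrix to a single time
#' series per trial, by averaging the forward-minus-backward difference
#' over a lag range (or taking the lag with maximum absolute evidence).
#'
#' @param result A \code{sliding_sequenceness} object.
#' @param lag_range Integer vector of lags (samples) to collapse over.
#' @param method \code{"mean"} (default) or \code{"max_abs"}.
#' @return Numeric vector indexed by window centre (see
#'   \code{result$centers}).
#' @export
collapse_lags <- function(result, lag_range, method = c("mean", "max_abs")) {
  method <- match.arg(method)
  if (length(lag_range) == 0L) stop("lag_range must be non-empty")
  if (any(lag_range < 1L) || any(lag_range > max(result$lags))) {
    stop("lag_range outside computed lags")
  }
  d <- result$difference[, lag_range, drop = FALSE]
  if (method == "mean") {
    rowMeans(d)
  } else {
    idx <- apply(abs(d), 1L, which.max)
    d[cbind(seq_len(nrow(d)), idx)]
  }
}

#' Mean sequenceness across per-arm transition matrices
#'
#' Computes the forward-minus-backward difference separately for each
#' arm's transition matrix and averages the differences, giving the mean
#' replay evidence across all paths.
#'
#' @param react Time x state reactivation matrix.
#' @param task_map A \code{\link{build_task_map}} object.
#' @param arms Arm names (default: all).
#' @param ... Passed to \code{\link{compute_sequenceness}}.
#' @return A data frame with columns \code{lag} and \code{difference}.
#' @export
mean_arm_sequenceness <- function(react, task_map = build_task_map(),
                                  arms = names(task_map$arms), ...) {
  per_arm <- lapply(arms, function(a) {
    compute_sequenceness(react, transition_matrix(task_map, a), ...)$difference
  })
  d <- rowMeans(do.call(cbind, per_arm))
  data.frame(lag = seq_along(d), difference = d)
}
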