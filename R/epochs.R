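#' Construct a sensor-epochs object
#'
#' Container for epoched multichannel time series: a numeric array of
#' dimension trials x channels x samples, a time axis relative to event
#' onset, a sampling rate (100 Hz by default) and per-trial labels or
#' metadata.
#'
#' @param data Numeric array [trials x channels x samples].
#' @param times Numeric vector of sample times in seconds (length =
#'   dim(data)[3]).
#' @param sfreq Sampling rate in Hz.
#' @param labels Vector or data frame of per-trial labels (length/nrow =
#'   dim(data)[1]), or NULL.
#' @return An object of class \code{sensor_epochs}.
#' @export
sensor_epochs <- function(data, times, sfreq = 100, labels = NULL) {
  stopifnot(length(dim(data)) == 3L, length(times) == dim(data)[3])
  if (!is.null(labels)) {
    n_lab <- if (is.data.frame(labels)) nrow(labels) else length(labels)
    if (n_lab != dim(data)[1]) stop("labels length must equal trial count")
  }
  if (any(!is.finite(data))) stop("epochs must not contain missing samples")
  structure(list(data = data, times = times, sfreq = sfreq, labels = labels),
            class = "sensor_epochs")
}

#' @export
print.sensor_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Sensor epochs: %d trials x %d channels x %d samples (%g Hz, %g to %g s)\n",
              d[1], d[2], d[3], x$sfreq, min(x$times), max(x$times)))
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1]

# nearest sample index for a time point
time_index <- function(epochs, t) {
  idx <- which.min(abs(epochs$times - t))
  if (abs(epochs$times[idx] - t) > 0.5 / epochs$sfreq + 1e-9) {
    stop("time ", t, " outside the epoch")
  }
  idx
}
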