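# Synthetic MEG-style data with known ground truth. The generators emulate
# the statistical structure the analyses assume -- stimulus-specific spatial
# patterns with a stereotyped temporal response, isolated reactivations,
# lagged sequential replay, and power series linearly coupled to
# reactivation strength -- on top of Gaussian sensor noise (optionally AR(1)
# in time).

#' Stimulus-specific spatial patterns and response kernel
#'
#' Draws one unit-norm spatial pattern (channel vector) per state plus a
#' Gaussian temporal response kernel shared across states. With hundreds of
#' channels, random unit vectors are near-orthogonal, emulating mutually
#' distinguishable stimulus-evoked field patterns.
#'
#' @param n_channels Number of sensors (default 272).
#' @param states State labels (default the 14 task states).
#' @param latency Response peak latency in seconds (default 0.2).
#' @param width Response Gaussian SD in seconds (default 0.05).
#' @param amplitude Peak response amplitude (default 1).
#' @param seed Integer seed.
#' @return Object of class \code{stimulus_patterns}: \code{patterns}
#'   (states x channels, unit rows), \code{kernel} (function of a time
#'   vector), plus the settings.
#' @export
stimulus_patterns <- function(n_channels = 272L, states = LETTERS[1:14],
                              latency = 0.2, width = 0.05, amplitude = 1,
                              seed = 1L) {
  W <- with_seed(seed, matrix(stats::rnorm(length(states) * n_channels),
                              length(states), n_channels))
  W <- W / sqrt(rowSums(W^2))
  rownames(W) <- states
  cosmax <- max(abs(tcrossprod(W)[lower.tri(diag(length(states)))]))
  if (cosmax >= 0.9) stop("patterns insufficiently distinguishable")
  kern <- function(t) amplitude * exp(-(t - latency)^2 / (2 * width^2))
  structure(list(patterns = W, kernel = kern, n_channels = n_channels,
                 states = states, latency = latency, width = width,
                 amplitude = amplitude, seed = seed),
            class = "stimulus_patterns")
}

noise_array <- function(n_trial, n_ch, n_samp, ar = 0) {
  x <- array(stats::rnorm(n_trial * n_ch * n_samp), c(n_trial, n_ch, n_samp))
  if (ar > 0) {
    scale <- sqrt(1 - ar^2)
    for (s in 2:n_samp) {
      x[, , s] <- ar * x[, , s - 1L] + scale * x[, , s]
    }
  }
  x
}

#' Generate synthetic localizer epochs
#'
#' Each trial presents one stimulus: its spatial pattern modulated by the
#' temporal response kernel, scaled by \code{snr}, plus unit-variance
#' sensor noise. Stimulus order is a balanced random permutation, so with
#' the default 900 trials each of the 14 stimuli appears about 64 times.
#'
#' @param patterns A \code{\link{stimulus_patterns}} object.
#' @param n_trials Number of trials (default 900).
#' @param snr Pattern amplitude relative to unit sensor noise (>= 0).
#' @param seed Integer seed.
#' @param sfreq Sampling rate (Hz).
#' @param epoch Epoch window in seconds (default 0 to 0.8).
#' @param ar AR(1) coefficient for temporally correlated noise (default 0).
#' @return A \code{\link{sensor_epochs}} object with per-trial stimulus
#'   labels.
#' @export
generate_localizer <- function(patterns, n_trials = 900L, snr = 1, seed = 1L,
                               sfreq = 100, epoch = c(0, 0.8), ar = 0) {
  if (snr < 0) stop("snr must be non-negative")
  states <- patterns$states
  times <- seq(epoch[1], epoch[2], by = 1 / sfreq)
  with_seed(seed, {
    labels <- sample(rep(states, length.out = n_trials))
    x <- noise_array(n_trials, patterns$n_channels, length(times), ar)
    k <- patterns$kernel(times)
    for (tr in seq_len(n_trials)) {
      x[tr, , ] <- x[tr, , ] +
        snr * outer(patterns$patterns[labels[tr], ], k)
    }
    sensor_epochs(x, times, sfreq, labels)
  })
}

#' Specify injectable replay events
#'
#' @param path Ordered state labels of the replayed path (e.g. an arm), or
#'   an arm name resolved against \code{\link{build_task_map}}.
#' @param lag Inter-state lag in seconds (10 to 200 ms).
#' @param direction \code{"forward"} or \code{"reverse"}.
#' @param onset Event onset in seconds; a length-2 vector is treated as a
#'   range from which onsets are drawn uniformly per event.
#' @param amplitude Pattern amplitude of each injected state pulse.
#' @param n_events Events per trial.
#' @param pulse_width Gaussian SD of each state pulse in seconds.
#' @return A \code{replay_spec} list.
#' @export
replay_spec <- function(path, lag = 0.04,
                        direction = c("forward", "reverse"),
                        onset = 1.5, amplitude = 1, n_events = 1L,
                        pulse_width = 0.01) {
  direction <- match.arg(direction)
  if (length(path) == 1L) {
    tm <- build_task_map()
    if (!path %in% names(tm$arms)) stop("unknown arm: ", path)
    path <- tm$arms[[path]]
  }
  if (lag < 0.01 - 1e-9 || lag > 0.2 + 1e-9) {
    stop("lag must be between 10 and 200 ms")
  }
  structure(list(path = path, lag = lag, direction = direction,
                 onset = onset, amplitude = amplitude,
                 n_events = as.integer(n_events),
                 pulse_width = pulse_width),
            class = "replay_spec")
}

#' Specify injectable isolated reactivations
#'
#' @param state A state label, or \code{"chosen_terminal"} /
#'   \code{"unchosen_terminal"} to resolve per trial against a behavior
#'   dataset.
#' @param times Times (seconds) at which the state's pattern is injected; a
#'   length-2 vector with \code{random = TRUE} is treated as a range.
#' @param amplitude Pattern amplitude.
#' @param random Draw \code{n_events} onsets uniformly from the
#'   \code{times} range instead of using fixed times.
#' @param n_events Number of events per trial when \code{random}.
#' @param pulse_width Gaussian SD of the pulse in seconds.
#' @return A \code{reactivation_spec} list.
#' @export
reactivation_spec <- function(state, times, amplitude = 1, random = FALSE,
                              n_events = 1L, pulse_width = 0.01) {
  structure(list(state = state, times = times, amplitude = amplitude,
                 random = random, n_events = as.integer(n_events),
                 pulse_width = pulse_width),
            class = "reactivation_spec")
}

resolve_state <- function(state, behavior, trial) {
  if (state == "chosen_terminal") {
    behavior$chosen_terminal[trial]
  } else if (state == "unchosen_terminal") {
    c(M = "N", N = "M")[[behavior$chosen_terminal[trial]]]
  } else {
    state
  }
}

add_pulse <- function(slice, pattern, times, center, width, amplitude) {
  pulse <- amplitude * exp(-(times - center)^2 / (2 * width^2))
  slice + outer(pattern, pulse)
}

#' Generate synthetic task-phase epochs
#'
#' One epoch per behavior trial: Gaussian sensor noise plus optional
#' isolated reactivations (a single state's pattern pulsed at given times)
#' and optional lagged sequential replay events (a path's state patterns
#' pulsed in order, forward or reverse, separated by the specified lag).
#'
#' @param behavior A \code{behavior_dataset} (one epoch per row).
#' @param patterns A \code{\link{stimulus_patterns}} object.
#' @param react A \code{\link{reactivation_spec}} or NULL.
#' @param replay A \code{\link{replay_spec}} or NULL.
#' @param snr Scales injected amplitudes relative to unit noise.
#' @param seed Integer seed.
#' @param sfreq Sampling rate (Hz).
#' @param duration Epoch duration in seconds (default 6, the planning
#'   phase; use 2.8 for the outcome phase).
#' @param ar AR(1) noise coefficient (default 0).
#' @return A \code{\link{sensor_epochs}} object; the behavior table is
#'   carried as labels.
#' @export
generate_task_epochs <- function(behavior, patterns, react = NULL,
                                 replay = NULL, snr = 1, seed = 1L,
                                 sfreq = 100, duration = 6, ar = 0) {
  n_tr <- nrow(behavior)
  times <- seq(0, duration - 1 / sfreq, by = 1 / sfreq)
  span_ok <- function(t0, spec_span) {
    if (any(t0 < 0) || any(t0 + spec_span > duration)) {
      stop("injection specification exceeds epoch bounds")
    }
  }
  with_seed(seed, {
    x <- noise_array(n_tr, patterns$n_channels, length(times), ar)
    for (tr in seq_len(n_tr)) {
      if (!is.null(react)) {
        st <- resolve_state(react$state, behavior, tr)
        tt <- if (react$random) {
          stats::runif(react$n_events, react$times[1], react$times[2])
        } else react$times
        span_ok(tt, 0)
        for (t0 in tt) {
          x[tr, , ] <- add_pulse(x[tr, , ], patterns$patterns[st, ], times,
                                 t0, react$pulse_width,
                                 snr * react$amplitude)
        }
      }
      if (!is.null(replay)) {
        path <- replay$path
        if (replay$direction == "reverse") path <- rev(path)
        span <- (length(path) - 1L) * replay$lag
        onsets <- if (length(replay$onset) == 2L) {
          stats::runif(replay$n_events, replay$onset[1], replay$onset[2])
        } else rep(replay$onset, replay$n_events)
        span_ok(onsets, span)
        for (t0 in onsets) {
          for (k in seq_along(path)) {
            x[tr, , ] <- add_pulse(x[tr, , ], patterns$patterns[path[k], ],
                                   times, t0 + (k - 1L) * replay$lag,
                                   replay$pulse_width,
                                   snr * replay$amplitude)
          }
        }
      }
    }
    sensor_epochs(x, times, sfreq, behavior)
  })
}

#' Generate power series coupled to reactivation strength
#'
#' Produces a trials x time matrix of band-limited power in which each
#' trial's level is a linear function of its reactivation strength inside
#' a temporal coupling window, plus Gaussian noise:
#' \code{power(trial, t) = baseline + beta * strength(trial) * window(t) +
#' noise}. Nonnegativity is enforced by clipping at zero; the default
#' baseline is high enough that clipping essentially never binds, keeping
#' the generative model linear.
#'
#' @param strength Numeric vector of per-trial reactivation strengths.
#' @param beta Coupling coefficient.
#' @param noise_sd Noise SD (>= 0).
#' @param seed Integer seed.
#' @param n_time Number of time points.
#' @param baseline Baseline power level (default 5).
#' @param window Numeric vector of length \code{n_time} weighting the
#'   coupling over time (default all ones).
#' @return A trials x time matrix of class \code{power_series} with a
#'   \code{"band"} attribute.
#' @export
generate_power_series <- function(strength, beta, noise_sd = 1, seed = 1L,
                                  n_time = 100L, baseline = 5,
                                  window = rep(1, n_time)) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(length(window) == n_time)
  n_tr <- length(strength)
  pw <- with_seed(seed, {
    noise <- matrix(stats::rnorm(n_tr * n_time, sd = noise_sd), n_tr, n_time)
    baseline + outer(strength, window) * beta + noise
  })
  pw <- pmax(pw, 0)
  structure(pw, band = "theta", class = c("power_series", "matrix", "array"))
}
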