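#' Build the canonical task map
#'
#' The task space comprises 14 states (labelled \code{A} to \code{N})
#' organised into four arms of four states each. Two arms are "learning"
#' arms (\code{B>F>J>M}, \code{C>G>K>N}) on which outcomes are experienced,
#' and two are "generalization" arms (\code{A>E>I>M}, \code{D>H>L>N}) on
#' which outcomes are never shown. Arms pair up by terminal state: the two
#' arms ending in \code{M} never compete with each other; learning trials
#' offer the two learning arms and generalization trials the two
#' generalization arms, so each choice is always between terminals \code{M}
#' and \code{N}.
#'
#' @return An object of class \code{task_map} with components
#'   \code{states} (character vector of 14 state labels), \code{arms}
#'   (named list of 4 character vectors, each a 4-state path),
#'   \code{arm_type} (named character, \code{"learning"} or
#'   \code{"generalization"}), \code{terminal} (named character, terminal
#'   state of each arm) and \code{pairing} (list giving the two arms offered
#'   on each trial type).
#' @export
#' @examples
#' tm <- build_task_map()
#' tm$arms$learning_M
build_task_map <- function() {
  arms <- list(
    generalization_M = c("A", "E", "I", "M"),
    learning_M       = c("B", "F", "J", "M"),
    learning_N       = c("C", "G", "K", "N"),
    generalization_N = c("D", "H", "L", "N")
  )
  arm_type <- c(
    generalization_M = "generalization",
    learning_M       = "learning",
    learning_N       = "learning",
    generalization_N = "generalization"
  )
  terminal <- vapply(arms, function(a) a[length(a)], character(1))
  structure(
    list(
      states   = LETTERS[1:14],
      arms     = arms,
      arm_type = arm_type,
      terminal = terminal,
      pairing  = list(
        learning       = c("learning_M", "learning_N"),
        generalization = c("generalization_M", "generalization_N")
      )
    ),
    class = "task_map"
  )
}

#' @export
print.task_map <- function(x, ...) {
  cat("Task map:", length(x$states), "states,", length(x$arms), "arms\n")
  for (nm in names(x$arms)) {
    cat(sprintf("  %-17s %s  (%s)\n", nm,
                paste(x$arms[[nm]], collapse = " > "), x$arm_type[nm]))
  }
  invisible(x)
}

#' State-to-state transition matrix for a set of arms
#'
#' Entry (i, j) is 1 if state j directly follows state i on one of the
#' selected arms, 0 otherwise. Terminal states have all-zero rows. The
#' reverse (backward) transition matrix is the transpose.
#'
#' @param task_map A \code{\link{build_task_map}} object.
#' @param arm_subset Character vector of arm names (default: all arms).
#' @return A 14 x 14 binary matrix with state labels as dimnames and an
#'   \code{"arms"} attribute recording the contributing arms.
#' @export
transition_matrix <- function(task_map, arm_subset = names(task_map$arms)) {
  stopifnot(inherits(task_map, "task_map"))
  if (length(arm_subset) == 0L) stop("arm_subset must be non-empty")
  unknown <- setdiff(arm_subset, names(task_map$arms))
  if (length(unknown) > 0L) {
    stop("unknown arm label(s): ", paste(unknown, collapse = ", "))
  }
  n <- length(task_map$states)
  T_mat <- matrix(0L, n, n, dimnames = list(task_map$states, task_map$states))
  for (arm in arm_subset) {
    path <- task_map$arms[[arm]]
    for (k in seq_len(length(path) - 1L)) {
      T_mat[path[k], path[k + 1L]] <- 1L
    }
  }
  attr(T_mat, "arms") <- arm_subset
  T_mat
}

#' Generate anticorrelated shock-probability random walks
#'
#' Shock probabilities for the two terminal states follow reflecting
#' Gaussian random walks whose innovations are negatively coupled, so that
#' the two series are moderately -- but not perfectly -- anticorrelated and
#' each terminal is the safer option on roughly half of trials. The default
#' coupling is calibrated so that the mean within-walk correlation of the
#' two series is about -0.57.
#'
#' @param n_trials Number of trials (>= 1).
#' @param step_sd Innovation standard deviation per trial (>= 0).
#' @param coupling Correlation of the two walks' innovations, in [-1, 1];
#'   negative values anticorrelate the walks.
#' @param bounds Length-2 numeric, reflection bounds inside [0, 1].
#' @param start Length-2 numeric, initial probabilities for M and N.
#' @param seed Integer seed; the walk is a pure function of its arguments.
#' @return A data frame of class \code{shock_walk} with columns
#'   \code{trial}, \code{p_shock_M}, \code{p_shock_N}; generator settings
#'   are kept in attributes.
#' @export
generate_shock_walk <- function(n_trials, step_sd = 0.07, coupling = -0.65,
                                bounds = c(0.05, 0.95),
                                start = c(0.5, 0.5), seed = 1L) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (step_sd < 0) stop("step_sd must be non-negative")
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2],
            bounds[1] >= 0, bounds[2] <= 1,
            abs(coupling) <= 1)
  p <- matrix(NA_real_, n_trials, 2L)
  cur <- pmin(pmax(start, bounds[1]), bounds[2])
  z <- with_seed(seed, matrix(stats::rnorm(2L * n_trials), n_trials, 2L))
  # couple innovations: e2 = coupling * e1 + sqrt(1 - coupling^2) * z2
  innov <- cbind(z[, 1L], coupling * z[, 1L] + sqrt(1 - coupling^2) * z[, 2L])
  for (t in seq_len(n_trials)) {
    if (t > 1L) cur <- reflect(cur + step_sd * innov[t - 1L, ], bounds)
    p[t, ] <- cur
  }
  out <- data.frame(trial = seq_len(n_trials),
                    p_shock_M = p[, 1L], p_shock_N = p[, 2L])
  attr(out, "settings") <- list(step_sd = step_sd, coupling = coupling,
                                bounds = bounds, start = start, seed = seed)
  class(out) <- c("shock_walk", "data.frame")
  out
}

# reflect values into [lo, hi] (repeatedly, in case of large excursions)
reflect <- function(x, bounds) {
  lo <- bounds[1]; hi <- bounds[2]
  span <- hi - lo
  # map onto a 2*span sawtooth
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  lo + y
}

#' Generate a randomized trial schedule
#'
#' Trials are labelled learning or generalization; the number of
#' generalization trials is \code{round(n_trials * prop_generalization)}
#' (round half up), and their positions are randomized. On each trial the
#' offered arms are the pair matching the trial type.
#'
#' @param n_trials Number of trials (> 0). Default 120.
#' @param prop_generalization Proportion of generalization trials in [0, 1];
#'   default 0.28.
#' @param seed Integer seed.
#' @param task_map Task map used to look up the arm pairing.
#' @return A data frame of class \code{trial_schedule} with columns
#'   \code{trial}, \code{trial_type}, \code{arm_1}, \code{arm_2}.
#' @export
generate_trial_schedule <- function(n_trials = 120L, prop_generalization = 0.28,
                                    seed = 1L, task_map = build_task_map()) {
  if (n_trials <= 0L) stop("n_trials must be positive")
  if (prop_generalization < 0 || prop_generalization > 1) {
    stop("prop_generalization must be in [0, 1]")
  }
  n_gen <- floor(n_trials * prop_generalization + 0.5)  # round half up
  type <- rep("learning", n_trials)
  idx <- with_seed(seed, sample.int(n_trials, n_gen))
  type[idx] <- "generalization"
  offered <- task_map$pairing[type]
  out <- data.frame(
    trial = seq_len(n_trials),
    trial_type = type,
    arm_1 = vapply(offered, `[`, character(1), 1L),
    arm_2 = vapply(offered, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  attr(out, "settings") <- list(prop_generalization = prop_generalization,
                                seed = seed)
  class(out) <- c("trial_schedule", "data.frame")
  out
}

#' Serialize a task map or schedule to JSON
#' @param x A \code{task_map} or \code{trial_schedule}.
#' @param path File path to write to.
#' @return \code{path}, invisibly.
#' @export
write_task_json <- function(x, path) {
  obj <- if (inherits(x, "task_map")) {
    list(states = x$states, arms = x$arms, arm_type = as.list(x$arm_type),
         pairing = x$pairing)
  } else if (inherits(x, "trial_schedule")) {
    as.list(as.data.frame(x))
  } else {
    stop("unsupported object")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a shock walk to TSV
#' @param walk A \code{shock_walk}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_walk_tsv <- function(walk, path) {
  utils::write.table(as.data.frame(walk), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a shock walk from TSV
#' @param path File path written by \code{\link{write_walk_tsv}}.
#' @return A \code{shock_walk} data frame.
#' @export
read_walk_tsv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  class(out) <- c("shock_walk", "data.frame")
  out
}
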