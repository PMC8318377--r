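#' Reinforcement-learning model parameters
#'
#' Parameters of the asymmetric Rescorla-Wagner model with generalization.
#' Values are shock expectancies in [0, 1] for the two terminal states,
#' updated by prediction errors on learning trials. \code{alpha_plus}
#' applies when the prediction error is positive (an unexpected shock under
#' shock = 1 coding) and \code{alpha_minus} when it is negative.
#' \code{G} scales how strongly learned terminal-state values drive choices
#' on generalization trials (0 = random choice, 1 = same influence as on
#' learning trials). \code{beta_softmax} is the softmax inverse temperature.
#'
#' The symmetric variant ties the two learning rates; the no-generalization
#' variant fixes \code{G = 0}.
#'
#' @param alpha_plus,alpha_minus Learning rates in [0, 1].
#' @param beta_softmax Inverse temperature, >= 0.
#' @param G Generalization weight in [0, 1].
#' @param asymmetric Logical; if \code{FALSE}, \code{alpha_minus} is forced
#'   equal to \code{alpha_plus}.
#' @param generalization Logical; if \code{FALSE}, \code{G} is forced to 0.
#' @param value_coding \code{"safety"} (default) scores each option by its
#'   safety value \code{1 - V}, preserving avoidance semantics;
#'   \code{"shock"} uses the shock expectancy \code{V} directly.
#' @return A \code{model_params} list.
#' @export
model_params <- function(alpha_plus = 0.3, alpha_minus = 0.3,
                         beta_softmax = 5, G = 0.5,
                         asymmetric = TRUE, generalization = TRUE,
                         value_coding = c("safety", "shock")) {
  value_coding <- match.arg(value_coding)
  if (!asymmetric) alpha_minus <- alpha_plus
  if (!generalization) G <- 0
  stopifnot(alpha_plus >= 0, alpha_plus <= 1,
            alpha_minus >= 0, alpha_minus <= 1,
            beta_softmax >= 0, G >= 0, G <= 1)
  structure(
    list(alpha_plus = alpha_plus, alpha_minus = alpha_minus,
         beta_softmax = beta_softmax, G = G,
         asymmetric = asymmetric, generalization = generalization,
         value_coding = value_coding),
    class = "model_params"
  )
}

coding_int <- function(params) if (params$value_coding == "shock") 1L else 0L

#' Prediction-error value update
#'
#' Applies one Rescorla-Wagner update to the chosen terminal's shock
#' expectancy: \code{delta = outcome - V}; \code{V' = V + alpha_plus *
#' delta} if \code{delta > 0}, \code{V + alpha_minus * delta} if
#' \code{delta < 0}, and no change when \code{delta = 0}. Only the chosen
#' terminal changes; only learning trials carry an outcome.
#'
#' @param state Named numeric \code{c(V_M = , V_N = )}, shock expectancies.
#' @param chosen_terminal \code{"M"} or \code{"N"}.
#' @param outcome 0 (safe) or 1 (shock).
#' @param params A \code{\link{model_params}} object.
#' @return Updated value state (same shape as \code{state}).
#' @export
update_value <- function(state, chosen_terminal, outcome, params) {
  if (is.na(outcome) || !(outcome %in% c(0, 1))) {
    stop("update_value requires an observed outcome (0 or 1)")
  }
  stopifnot(chosen_terminal %in% c("M", "N"))
  key <- paste0("V_", chosen_terminal)
  delta <- outcome - state[[key]]
  alpha <- if (delta > 0) params$alpha_plus else params$alpha_minus
  state[[key]] <- state[[key]] + alpha * delta
  state
}

#' Probability of choosing the M-terminal arm
#'
#' On generalization trials both values are first shrunk towards 0.5 by
#' \code{G}. Each option o then gets a score
#' \code{exp(beta * u_o) / (exp(beta * u_o) + exp(beta * (1 - u_o)))}
#' with \code{u_o} the option's decision value (safety value \code{1 - V}
#' by default), and the two scores are renormalized to yield the choice
#' probability.
#'
#' @param state Named numeric \code{c(V_M = , V_N = )}.
#' @param trial_type \code{"learning"} or \code{"generalization"}.
#' @param params A \code{\link{model_params}} object.
#' @return Probability in (0, 1) of choosing the arm ending in M.
#' @export
choice_probability <- function(state, trial_type, params) {
  v <- c(state[["V_M"]], state[["V_N"]])
  if (trial_type == "generalization") v <- 0.5 + (v - 0.5) * params$G
  u <- if (params$value_coding == "safety") 1 - v else v
  s <- stats::plogis(params$beta_softmax * (2 * u - 1))
  s[1] / (s[1] + s[2])
}

#' Simulate choices from the learning model
#'
#' Runs the model forward over a trial schedule. Learning trials draw the
#' choice from the model's choice probability, draw the outcome from the
#' chosen terminal's shock probability, and update values; generalization
#' trials draw choices through the G-scaled values and never update
#' (no outcome is presented).
#'
#' @param params A \code{\link{model_params}} object.
#' @param schedule A \code{\link{generate_trial_schedule}} data frame.
#' @param walks A \code{\link{generate_shock_walk}} data frame of the same
#'   length.
#' @param seed Integer seed.
#' @param task_map Task map for arm/terminal lookups.
#' @param id Participant identifier stored with the dataset.
#' @return A data frame of class \code{behavior_dataset} with columns
#'   \code{trial}, \code{trial_type}, \code{chosen_arm},
#'   \code{chosen_terminal}, \code{outcome} (NA on generalization trials),
#'   \code{p_M} (model choice probability), \code{v_M}, \code{v_N}
#'   (pre-choice values) and \code{pe} (prediction error, NA off learning
#'   trials). Generating parameters are stored in the
#'   \code{"generating_params"} attribute.
#' @export
simulate_choices <- function(params, schedule, walks, seed = 1L,
                             task_map = build_task_map(), id = "sim") {
  if (nrow(schedule) != nrow(walks)) {
    stop("schedule and walks must have the same number of trials")
  }
  n <- nrow(schedule)
  u <- with_seed(seed, matrix(stats::runif(2L * n), n, 2L))
  v <- c(V_M = 0.5, V_N = 0.5)
  choice <- character(n); arm <- character(n)
  outcome <- rep(NA_real_, n); p_M <- numeric(n)
  v_M <- numeric(n); v_N <- numeric(n); pe <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    v_M[t] <- v[["V_M"]]; v_N[t] <- v[["V_N"]]
    type <- schedule$trial_type[t]
    p <- choice_probability(v, type, params)
    p_M[t] <- p
    term <- if (u[t, 1L] < p) "M" else "N"
    choice[t] <- term
    offered <- c(schedule$arm_1[t], schedule$arm_2[t])
    arm[t] <- offered[match(term, task_map$terminal[offered])]
    if (type == "learning") {
      p_shock <- if (term == "M") walks$p_shock_M[t] else walks$p_shock_N[t]
      outcome[t] <- as.numeric(u[t, 2L] < p_shock)
      pe[t] <- outcome[t] - v[[paste0("V_", term)]]
      v <- update_value(v, term, outcome[t], params)
    }
  }
  out <- data.frame(
    trial = schedule$trial, trial_type = schedule$trial_type,
    chosen_arm = arm, chosen_terminal = choice, outcome = outcome,
    p_M = p_M, v_M = v_M, v_N = v_N, pe = pe,
    stringsAsFactors = FALSE
  )
  attr(out, "id") <- id
  attr(out, "generating_params") <- params
  class(out) <- c("behavior_dataset", "data.frame")
  out
}

behavior_inputs <- function(dataset) {
  list(
    trial_type = as.integer(dataset$trial_type == "generalization"),
    choice = as.integer(dataset$chosen_terminal == "M"),
    outcome = ifelse(is.na(dataset$outcome), -1, dataset$outcome)
  )
}

#' Per-trial log-likelihood of observed choices
#'
#' Deterministically replays the value-learning equations against the
#' observed choices and outcomes and returns each trial's log probability
#' of the observed choice under \code{params}.
#'
#' @param dataset A \code{behavior_dataset}.
#' @param params A \code{\link{model_params}} object.
#' @return Numeric vector, one log-likelihood per trial.
#' @export
log_likelihood <- function(dataset, params) {
  inp <- behavior_inputs(dataset)
  res <- .behavior_forward(inp$trial_type, inp$choice, inp$outcome,
                           params$alpha_plus, params$alpha_minus,
                           params$beta_softmax, params$G,
                           coding_int(params))
  as.numeric(res$ll)
}

#' Model-implied value and prediction-error trajectory
#'
#' Replays the learning equations against a dataset's observed choices and
#' outcomes, returning the pre-choice values and the prediction error on
#' each learning trial (outcome minus expected value; NA on generalization
#' trials, which present no outcome).
#'
#' @inheritParams log_likelihood
#' @return A data frame with columns \code{trial}, \code{v_M}, \code{v_N},
#'   \code{pe}, \code{p_M}.
#' @export
value_trajectory <- function(dataset, params) {
  inp <- behavior_inputs(dataset)
  res <- .behavior_forward(inp$trial_type, inp$choice, inp$outcome,
                           params$alpha_plus, params$alpha_minus,
                           params$beta_softmax, params$G,
                           coding_int(params))
  data.frame(trial = dataset$trial, v_M = res$V[, 1L], v_N = res$V[, 2L],
             pe = as.numeric(res$pe), p_M = as.numeric(res$p_M))
}

#' Model-agnostic choice consistency index
#'
#' The fraction of generalization trials on which the chosen terminal
#' matches the terminal chosen on the most recent preceding learning trial.
#' Values near 1 indicate choices consistent with carrying learned values
#' over to the never-experienced arms; 0.5 is the chance level under random
#' generalization choices.
#'
#' @param dataset A \code{behavior_dataset}.
#' @return Proportion in [0, 1].
#' @export
consistency_index <- function(dataset) {
  is_gen <- dataset$trial_type == "generalization"
  last_learn <- rep(NA_character_, nrow(dataset))
  cur <- NA_character_
  for (t in seq_len(nrow(dataset))) {
    last_learn[t] <- cur
    if (!is_gen[t]) cur <- dataset$chosen_terminal[t]
  }
  valid <- which(is_gen & !is.na(last_learn))
  if (length(valid) == 0L) {
    stop("no generalization trial preceded by a learning trial")
  }
  mean(dataset$chosen_terminal[valid] == last_learn[valid])
}

#' Write a behavior dataset to TSV
#' @param dataset A \code{behavior_dataset}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_behavior_tsv <- function(dataset, path) {
  utils::write.table(as.data.frame(dataset), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a behavior dataset from TSV
#' @param path File path written by \code{\link{write_behavior_tsv}}.
#' @param id Participant identifier.
#' @return A \code{behavior_dataset}.
#' @export
read_behavior_tsv <- function(path, id = basename(path)) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  attr(out, "id") <- id
  class(out) <- c("behavior_dataset", "data.frame")
  out
}
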