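# Hierarchical Bayesian fitting of the learning model.
#
# Parameters are transformed to an unconstrained scale (logit for the
# learning rates and G, log for beta) where each participant's vector gets
# a Normal group prior. Fitting alternates per-participant MAP estimation
# (quasi-Newton) with updates of the group mean and SD that account for
# per-participant posterior uncertainty (an EM scheme); each participant's
# posterior is approximated by a Gaussian centred on the MAP with
# covariance from the local curvature, from which posterior draws and
# pointwise log-likelihoods are obtained.

variant_spec <- function(variant) {
  variant <- match.arg(variant, c("asym_G", "sym_G", "asym_noG", "sym_noG"))
  switch(variant,
    asym_G   = list(variant = variant, names = c("alpha_plus", "alpha_minus", "beta", "G")),
    sym_G    = list(variant = variant, names = c("alpha", "beta", "G")),
    asym_noG = list(variant = variant, names = c("alpha_plus", "alpha_minus", "beta")),
    sym_noG  = list(variant = variant, names = c("alpha", "beta"))
  )
}

# map an active transformed vector to the natural (ap, am, beta, G) scale
natural_from_theta <- function(theta, spec) {
  nm <- spec$names
  inv <- stats::plogis
  if ("alpha" %in% nm) {
    a <- inv(theta[match("alpha", nm)])
    ap <- a; am <- a
  } else {
    ap <- inv(theta[match("alpha_plus", nm)])
    am <- inv(theta[match("alpha_minus", nm)])
  }
  beta <- exp(theta[match("beta", nm)])
  G <- if ("G" %in% nm) inv(theta[match("G", nm)]) else 0
  c(alpha_plus = ap, alpha_minus = am, beta = beta, G = G)
}

theta_init <- function(spec) {
  init <- c(alpha = stats::qlogis(0.3), alpha_plus = stats::qlogis(0.3),
            alpha_minus = stats::qlogis(0.3), beta = log(3), G = 0)
  unname(init[spec$names])
}

participant_nll <- function(theta, inp, spec, value_coding) {
  nat <- natural_from_theta(theta, spec)
  .behavior_nll(inp$trial_type, inp$choice, inp$outcome,
                nat[1L], nat[2L], nat[3L], nat[4L], value_coding)
}

#' Fit the learning model hierarchically across participants
#'
#' Fits one of four model variants (asymmetric or symmetric learning rates,
#' with or without the generalization parameter G) to a list of behavior
#' datasets using an approximate hierarchical Bayesian scheme: Normal group
#' priors on logit/log-transformed parameters, per-participant Gaussian
#' (Laplace) posterior approximations, and EM updates of the group
#' hyperparameters. Posterior draws from the per-participant Gaussians
#' provide parameter summaries and the pointwise log-likelihood matrix used
#' by \code{\link{waic}}.
#'
#' @param datasets List of \code{behavior_dataset} objects (>= 2).
#' @param variant One of \code{"asym_G"}, \code{"sym_G"},
#'   \code{"asym_noG"}, \code{"sym_noG"}.
#' @param n_iter Maximum EM iterations.
#' @param n_draws Posterior draws per participant.
#' @param seed Integer seed for the posterior draws.
#' @param value_coding Decision-value coding, as in
#'   \code{\link{model_params}}.
#' @param tol Convergence tolerance on the group-mean update.
#' @return An object of class \code{behavior_fit}: per-participant
#'   posterior summaries (\code{$participants}), group hyperparameters
#'   (\code{$group}), the stacked pointwise log-likelihood draw matrix
#'   (\code{$ll_draws}, draws x total trials), \code{$waic}, and a
#'   \code{$converged} flag (non-convergence is reported, never silent).
#' @export
fit_hierarchical <- function(datasets, variant = "asym_G", n_iter = 25L,
                             n_draws = 1000L, seed = 1L,
                             value_coding = c("safety", "shock"),
                             tol = 1e-3) {
  if (length(datasets) < 2L) stop("need at least 2 participants")
  value_coding <- match.arg(value_coding)
  vc <- if (value_coding == "shock") 1L else 0L
  spec <- variant_spec(variant)
  k <- length(spec$names)
  P <- length(datasets)
  inputs <- lapply(datasets, behavior_inputs)

  mu <- theta_init(spec)
  sd_g <- rep(1, k)
  theta <- matrix(rep(mu, each = P), P, k)
  covs <- vector("list", P)
  converged <- FALSE

  for (iter in seq_len(n_iter)) {
    for (i in seq_len(P)) {
      obj <- function(th) {
        participant_nll(th, inputs[[i]], spec, vc) +
          sum(((th - mu) / sd_g)^2) / 2
      }
      opt <- stats::optim(theta[i, ], obj, method = "BFGS",
                          control = list(maxit = 200L))
      theta[i, ] <- opt$par
      H <- stats::optimHess(opt$par, obj)
      covs[[i]] <- robust_inverse(H)
    }
    mu_new <- colMeans(theta)
    var_new <- colMeans((theta - rep(mu_new, each = P))^2) +
      colMeans(t(vapply(covs, diag, numeric(k))))
    sd_new <- pmax(sqrt(var_new), 0.1)
    delta <- max(abs(mu_new - mu))
    mu <- mu_new; sd_g <- sd_new
    if (delta < tol) { converged <- TRUE; break }
  }

  # posterior draws and pointwise log-likelihoods
  draws_nat <- vector("list", P)
  ll_list <- vector("list", P)
  participants <- vector("list", P)
  for (i in seq_len(P)) {
    d <- with_seed(child_seed(seed, i),
                   rmvnorm_chol(n_draws, theta[i, ], covs[[i]]))
    nat <- t(apply(d, 1L, natural_from_theta, spec = spec))
    colnames(nat) <- c("alpha_plus", "alpha_minus", "beta", "G")
    draws_nat[[i]] <- nat
    ll_list[[i]] <- .behavior_ll_draws(inputs[[i]]$trial_type,
                                       inputs[[i]]$choice,
                                       inputs[[i]]$outcome, nat, vc)
    mean_nat <- colMeans(nat)
    hpdi95 <- apply(nat, 2L, hpdi, prob = 0.95)
    participants[[i]] <- list(
      id = attr(datasets[[i]], "id") %||% i,
      mean = mean_nat,
      hpdi_lower = hpdi95[1L, ], hpdi_upper = hpdi95[2L, ],
      map_transformed = theta[i, ]
    )
  }
  ll_draws <- do.call(cbind, ll_list)

  fit <- structure(
    list(variant = spec$variant, param_names = spec$names,
         participants = participants,
         group = list(mean = stats::setNames(mu, spec$names),
                      sd = stats::setNames(sd_g, spec$names)),
         draws = draws_nat, ll_draws = ll_draws,
         n_iter_used = iter, converged = converged,
         value_coding = value_coding),
    class = "behavior_fit"
  )
  fit$waic <- waic(fit)$waic
  if (!converged) {
    warning("hierarchical fit did not meet the convergence tolerance after ",
            n_iter, " iterations")
  }
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

robust_inverse <- function(H) {
  k <- nrow(H)
  out <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out)) || any(diag(out) <= 0)) {
    out <- tryCatch(solve((H + t(H)) / 2 + diag(1e-4, k)),
                    error = function(e) diag(1e2, k))
    if (any(diag(out) <= 0)) out <- diag(1e2, k)
  }
  out
}

#' Posterior-mean parameter table of a hierarchical fit
#' @param fit A \code{behavior_fit}.
#' @return Data frame, one row per participant, columns
#'   \code{alpha_plus}, \code{alpha_minus}, \code{beta}, \code{G}.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "behavior_fit"))
  out <- as.data.frame(t(vapply(fit$participants, `[[`, numeric(4), "mean")))
  out$id <- vapply(fit$participants, function(p) as.character(p$id),
                   character(1))
  out[, c("id", "alpha_plus", "alpha_minus", "beta", "G")]
}

#' @export
print.behavior_fit <- function(x, ...) {
  cat("Hierarchical fit, variant", x$variant, "-", length(x$participants),
      "participants\n")
  cat(sprintf("  WAIC %.2f  (converged: %s, %d EM iterations)\n",
              x$waic, x$converged, x$n_iter_used))
  invisible(x)
}

#' Watanabe-Akaike information criterion
#'
#' Computes \code{WAIC = -2 * (lppd - p_waic)} from a matrix of pointwise
#' log-likelihood draws (draws x observations), with the effective number
#' of parameters \code{p_waic} estimated as the sum over observations of
#' the posterior variance of the log-likelihood. Lower is better.
#'
#' @param fit A \code{behavior_fit}, or a numeric draws x observations
#'   matrix of pointwise log-likelihoods.
#' @return A list with \code{waic}, \code{se} (sampling SE over
#'   observations), \code{lppd} and \code{p_waic}.
#' @export
waic <- function(fit) {
  ll <- if (inherits(fit, "behavior_fit")) fit$ll_draws else as.matrix(fit)
  if (nrow(ll) < 2L) stop("need at least 2 posterior draws")
  # stable log-mean-exp by column
  m <- apply(ll, 2L, max)
  lppd_i <- m + log(colMeans(exp(sweep(ll, 2L, m))))
  p_i <- apply(ll, 2L, stats::var)
  elpd_i <- lppd_i - p_i
  n <- ncol(ll)
  list(waic = -2 * sum(elpd_i),
       se = 2 * sqrt(n * stats::var(elpd_i)),
       lppd = sum(lppd_i), p_waic = sum(p_i))
}
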