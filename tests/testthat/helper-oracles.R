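# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations they check.

# sequenceness: explicit loop over transition pairs and lags
bf_sequenceness <- function(react, T_mat, max_lag = 20L) {
  n_t <- nrow(react)
  n_s <- ncol(react)
  fwd <- bwd <- numeric(max_lag)
  for (d in seq_len(max_lag)) {
    f_vals <- c()
    b_vals <- c()
    for (i in seq_len(n_s)) for (j in seq_len(n_s)) {
      if (T_mat[i, j] == 1) {
        past_i <- react[1:(n_t - d), i]
        pres_j <- react[(d + 1):n_t, j]
        f_vals <- c(f_vals, if (sd(past_i) == 0 || sd(pres_j) == 0) 0
                    else cor(past_i, pres_j))
        past_j <- react[1:(n_t - d), j]
        pres_i <- react[(d + 1):n_t, i]
        b_vals <- c(b_vals, if (sd(past_j) == 0 || sd(pres_i) == 0) 0
                    else cor(past_j, pres_i))
      }
    }
    fwd[d] <- mean(f_vals)
    bwd[d] <- mean(b_vals)
  }
  data.frame(lag = seq_len(max_lag), forward = fwd, backward = bwd,
             difference = fwd - bwd)
}

# trial-by-trial replay of the learning rule and choice rule
bf_loglik <- function(dataset, params) {
  vM <- 0.5
  vN <- 0.5
  ll <- numeric(nrow(dataset))
  for (t in seq_len(nrow(dataset))) {
    v <- c(vM, vN)
    if (dataset$trial_type[t] == "generalization") {
      v <- 0.5 + (v - 0.5) * params$G
    }
    u <- 1 - v
    s <- exp(params$beta_softmax * u) /
      (exp(params$beta_softmax * u) + exp(params$beta_softmax * (1 - u)))
    pM <- s[1] / (s[1] + s[2])
    p_obs <- if (dataset$chosen_terminal[t] == "M") pM else 1 - pM
    ll[t] <- log(p_obs)
    if (dataset$trial_type[t] == "learning") {
      if (dataset$chosen_terminal[t] == "M") {
        delta <- dataset$outcome[t] - vM
        a <- if (delta > 0) params$alpha_plus else params$alpha_minus
        vM <- vM + a * delta
      } else {
        delta <- dataset$outcome[t] - vN
        a <- if (delta > 0) params$alpha_plus else params$alpha_minus
        vN <- vN + a * delta
      }
    }
  }
  ll
}

# WAIC from first principles on a draws x observations matrix
bf_waic <- function(ll) {
  lppd <- 0
  p_waic <- 0
  for (i in seq_len(ncol(ll))) {
    lppd <- lppd + log(mean(exp(ll[, i])))
    p_waic <- p_waic + var(ll[, i])
  }
  -2 * (lppd - p_waic)
}

# narrowest interval containing prob of the draws, O(n^2) scan
bf_hpdi <- function(draws, prob) {
  x <- sort(draws)
  n <- length(x)
  m <- max(1, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  best <- c(-Inf, Inf)
  for (i in 1:(n - m)) {
    if (x[i + m] - x[i] < best[2] - best[1]) best <- c(x[i], x[i + m])
  }
  best
}
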