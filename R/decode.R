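# Stimulus decoding: binary temporal-generalization classifiers and
# one-versus-rest state classifiers, trained on localizer epochs and
# applied to task epochs. Classifiers are L1-penalized logistic
# regressions (glmnet) on standardized, PCA-reduced sensor data, with
# penalties chosen by random search over half-Cauchy draws.

half_cauchy <- function(n, gamma) abs(stats::rcauchy(n, 0, gamma))

# stratified fold assignment
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

scale_stats <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

apply_scale <- function(X, st) sweep(sweep(X, 2L, st$mu), 2L, st$sd, "/")

#' Train a grid of binary classifiers across localizer training times
#'
#' For each training time (by default every sample from 0 to 800 ms after
#' stimulus onset), fits a pipeline of standardization, PCA (50
#' components) and L1-penalized logistic regression discriminating the two
#' states, with the penalty chosen by random search over draws from a
#' half-Cauchy distribution (scale 5), evaluated by stratified 3-fold
#' cross-validation.
#'
#' @param localizer A \code{\link{sensor_epochs}} object with stimulus
#'   labels.
#' @param state_pair Character vector of two state labels (e.g.
#'   \code{c("M", "N")}).
#' @param train_times Times (seconds) to train at; default all samples in
#'   [0, 0.8].
#' @param n_components PCA components (default 50, capped by data rank).
#' @param n_search Random-search draws (default 100).
#' @param folds Cross-validation folds (default 3).
#' @param gamma Half-Cauchy scale for the penalty search (default 5).
#' @param seed Integer seed; fixing it reproduces hyperparameters and
#'   weights exactly.
#' @return Object of class \code{classifier_grid} with one fitted pipeline
#'   per training time (\code{$models}), the training times
#'   (\code{$times}) and cross-validated accuracies (\code{$cv_accuracy}).
#' @export
train_binary_grid <- function(localizer, state_pair, train_times = NULL,
                              n_components = 50L, n_search = 100L,
                              folds = 3L, gamma = 5, seed = 1L) {
  stopifnot(inherits(localizer, "sensor_epochs"), length(state_pair) == 2L)
  labels <- localizer$labels
  keep <- which(labels %in% state_pair)
  if (length(unique(labels[keep])) < 2L) {
    stop("both states must be present in the localizer labels")
  }
  if (min(table(labels[keep])) < 10L) {
    stop("need at least 10 exemplars of each state")
  }
  if (is.null(train_times)) {
    train_times <- localizer$times[localizer$times >= 0 &
                                     localizer$times <= 0.8 + 1e-9]
  }
  lv <- sort(state_pair)
  y <- as.integer(labels[keep] == lv[2L])
  n <- length(keep)
  with_seed(seed, {
    # draws are penalty strengths; glmnet's lambda is per-observation
    lam <- sort(unique(pmax(half_cauchy(n_search, gamma) / n, 1e-4)),
                decreasing = TRUE)
    fold <- stratified_folds(y, folds)
    models <- vector("list", length(train_times))
    cv_acc <- numeric(length(train_times))
    for (k in seq_along(train_times)) {
      s_idx <- time_index(localizer, train_times[k])
      X <- localizer$data[keep, , s_idx, drop = TRUE]
      st <- scale_stats(X)
      Xs <- apply_scale(X, st)
      ncmp <- min(n_components, ncol(Xs), n - 1L)
      pca <- stats::prcomp(Xs, center = FALSE, rank. = ncmp)
      Z <- pca$x
      acc <- matrix(NA_real_, folds, length(lam))
      for (f in seq_len(folds)) {
        tr <- fold != f
        fit <- glmnet::glmnet(Z[tr, , drop = FALSE], y[tr],
                              family = "binomial", lambda = lam,
                              standardize = FALSE)
        p <- stats::predict(fit, Z[!tr, , drop = FALSE], type = "response")
        acc[f, seq_len(ncol(p))] <- colMeans((p > 0.5) == y[!tr])
      }
      mean_acc <- colMeans(acc)
      best <- which.max(mean_acc)  # ties favour the stronger penalty
      fit <- glmnet::glmnet(Z, y, family = "binomial", lambda = lam,
                            standardize = FALSE)
      cf <- stats::coef(fit, s = lam[best])
      models[[k]] <- list(
        scale = st, rotation = pca$rotation,
        a0 = cf[1L], beta = as.numeric(cf[-1L]),
        lambda = lam[best], levels = lv
      )
      cv_acc[k] <- mean_acc[best]
    }
    structure(list(times = train_times, models = models,
                   cv_accuracy = cv_acc, state_pair = lv,
                   n_channels = dim(localizer$data)[2L], seed = seed),
              class = "classifier_grid")
  })
}

predict_binary <- function(model, X) {
  Z <- apply_scale(X, model$scale) %*% model$rotation
  stats::plogis(model$a0 + as.numeric(Z %*% model$beta))
}

#' Temporal generalization: apply a classifier grid across task time
#'
#' Applies every training-time classifier to every task time point and
#' scores, per cell, the accuracy with which the classifier predicts the
#' chosen terminal state. Cells significantly below chance indicate
#' reactivation of the opposite (unchosen) state.
#'
#' @param grid A \code{\link{train_binary_grid}} object.
#' @param task A \code{\link{sensor_epochs}} object with the same
#'   channels.
#' @param chosen_labels Character vector, the chosen state per trial.
#' @param task_times Times (seconds) to test at; default all task samples.
#' @return An \code{accuracy_map}: matrix [training time x task time] with
#'   dim names in ms, and the per-trial probability assigned to the chosen
#'   state in the \code{"prob_chosen"} attribute
#'   (trials x train x task array).
#' @export
temporal_generalization <- function(grid, task, chosen_labels,
                                    task_times = NULL) {
  if (dim(task$data)[2L] != grid$n_channels) {
    stop("channel count differs between training data and task epochs")
  }
  if (is.null(task_times)) task_times <- task$times
  n_tr <- n_trials(task)
  stopifnot(length(chosen_labels) == n_tr)
  lv <- grid$state_pair
  y <- as.integer(chosen_labels == lv[2L])
  acc <- matrix(NA_real_, length(grid$times), length(task_times))
  prob <- array(NA_real_, c(n_tr, length(grid$times), length(task_times)))
  for (s in seq_along(task_times)) {
    X <- task$data[, , time_index(task, task_times[s]), drop = TRUE]
    if (n_tr == 1L) X <- matrix(X, 1L)
    for (k in seq_along(grid$times)) {
      p <- predict_binary(grid$models[[k]], X)
      acc[k, s] <- mean((p > 0.5) == y)
      prob[, k, s] <- ifelse(y == 1L, p, 1 - p)
    }
  }
  dimnames(acc) <- list(train_ms = round(grid$times * 1000),
                        task_ms = round(task_times * 1000))
  structure(acc, prob_chosen = prob, train_times = grid$times,
            task_times = task_times, class = c("accuracy_map", "matrix", "array"))
}

#' Train one-versus-rest state classifiers at a single training time
#'
#' Embeds each localizer trial's data from 50 ms either side of the
#' training time (11 samples at 100 Hz), reduces the flattened window by
#' temporal PCA, standardizes, and fits one L1-penalized logistic
#' classifier per state against all others with balanced sample weights.
#' The number of components (uniform on [30, 60]) and the penalty
#' (half-Cauchy, scale 5) are tuned jointly by random search with 3-fold
#' cross-validation on multiclass accuracy.
#'
#' @param localizer A \code{\link{sensor_epochs}} with all 14 states.
#' @param train_time Training time in seconds (e.g. 0.52).
#' @param embed Samples either side of the training time (default 5).
#' @param comp_range Range of PCA components searched (default 30 to 60).
#' @param n_search Random-search iterations (default 100).
#' @param folds Cross-validation folds (default 3).
#' @param gamma Half-Cauchy scale (default 5).
#' @param seed Integer seed.
#' @return Object of class \code{state_classifiers} with the fitted
#'   projection and per-state coefficients, the selected hyperparameters
#'   and the cross-validated multiclass accuracy.
#' @export
train_state_classifiers <- function(localizer, train_time, embed = 5L,
                                    comp_range = c(30L, 60L),
                                    n_search = 100L, folds = 3L, gamma = 5,
                                    seed = 1L) {
  stopifnot(inherits(localizer, "sensor_epochs"))
  states <- sort(unique(localizer$labels))
  idx <- time_index(localizer, train_time)
  n_samp <- dim(localizer$data)[3L]
  if (idx - embed < 1L || idx + embed > n_samp) {
    stop("train_time too close to the epoch edge for the temporal embedding")
  }
  X <- embed_window(localizer$data, idx, embed)
  y_all <- localizer$labels
  n <- nrow(X)
  with_seed(seed, {
    comp_draws <- pmin(round(stats::runif(n_search, comp_range[1L], comp_range[2L])),
                       min(ncol(X), n - 2L))
    lam_draws <- pmax(half_cauchy(n_search, gamma) / n, 1e-4)
    fold <- stratified_folds(y_all, folds)
    max_comp <- max(comp_draws)
    correct <- matrix(0, folds, n_search)
    for (f in seq_len(folds)) {
      tr <- fold != f
      ctr <- colMeans(X[tr, , drop = FALSE])
      pca <- stats::prcomp(X[tr, , drop = FALSE], center = TRUE,
                           rank. = max_comp)
      Ztr_full <- pca$x
      Zte_full <- sweep(X[!tr, , drop = FALSE], 2L, ctr) %*% pca$rotation
      for (ncmp in unique(comp_draws)) {
        sel <- which(comp_draws == ncmp)
        lam <- sort(unique(lam_draws[sel]), decreasing = TRUE)
        st <- scale_stats(Ztr_full[, seq_len(ncmp), drop = FALSE])
        Ztr <- apply_scale(Ztr_full[, seq_len(ncmp), drop = FALSE], st)
        Zte <- apply_scale(Zte_full[, seq_len(ncmp), drop = FALSE], st)
        pr <- array(NA_real_, c(nrow(Zte), length(lam), length(states)))
        for (j in seq_along(states)) {
          yb <- as.integer(y_all[tr] == states[j])
          w <- ifelse(yb == 1L, sum(tr) / (2 * sum(yb)),
                      sum(tr) / (2 * sum(1 - yb)))
          fit <- glmnet::glmnet(Ztr, yb, family = "binomial", weights = w,
                                lambda = lam, standardize = FALSE)
          p <- stats::predict(fit, Zte, type = "response")
          pr[, seq_len(ncol(p)), j] <- p
        }
        for (li in seq_along(lam)) {
          pm <- matrix(pr[, li, ], ncol = length(states))
          pred <- states[apply(pm, 1L, which.max)]
          hits <- sum(pred == y_all[!tr])
          correct[f, sel[lam_draws[sel] == lam[li]]] <- hits
        }
      }
    }
    cv_acc <- colSums(correct) / n
    best <- which.max(cv_acc)
    ncmp <- comp_draws[best]; lambda <- lam_draws[best]
    ctr <- colMeans(X)
    pca <- stats::prcomp(X, center = TRUE, rank. = ncmp)
    st <- scale_stats(pca$x)
    Z <- apply_scale(pca$x, st)
    coefs <- matrix(NA_real_, ncmp + 1L, length(states),
                    dimnames = list(NULL, states))
    for (j in seq_along(states)) {
      yb <- as.integer(y_all == states[j])
      w <- ifelse(yb == 1L, n / (2 * sum(yb)), n / (2 * sum(1 - yb)))
      fit <- glmnet::glmnet(Z, yb, family = "binomial", weights = w,
                            lambda = sort(unique(c(lambda, lam_draws)),
                                          decreasing = TRUE),
                            standardize = FALSE)
      coefs[, j] <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
    }
    structure(
      list(states = states, train_time = train_time, embed = embed,
           center = ctr, rotation = pca$rotation, scale = st,
           coefs = coefs, n_components = ncmp, lambda = lambda,
           cv_accuracy = max(cv_acc), n_channels = dim(localizer$data)[2L],
           seed = seed),
      class = "state_classifiers"
    )
  })
}

# flatten the [idx - embed, idx + embed] window of every trial:
# columns ordered channel-major within each time offset
embed_window <- function(data, idx, embed) {
  n_tr <- dim(data)[1L]; n_ch <- dim(data)[2L]
  offs <- (-embed):embed
  out <- matrix(NA_real_, n_tr, n_ch * length(offs))
  for (o in seq_along(offs)) {
    out[, ((o - 1L) * n_ch + 1L):(o * n_ch)] <- data[, , idx + offs[o]]
  }
  out
}

#' Predict state labels for epochs at a fixed time point
#'
#' Applies the one-versus-rest state classifiers at a single time point of
#' each epoch (using the classifiers' temporal embedding), returning
#' normalized per-state probabilities and the predicted label per trial.
#' Useful for evaluating decoding accuracy on held-out localizer epochs.
#'
#' @param object A \code{\link{train_state_classifiers}} object.
#' @param epochs A \code{\link{sensor_epochs}}.
#' @param time Time point in seconds (default: the training time).
#' @param ... Unused.
#' @return A list with \code{prob} (trials x states matrix) and
#'   \code{label} (character vector).
#' @export
predict.state_classifiers <- function(object, epochs, time = NULL, ...) {
  if (is.null(time)) time <- object$train_time
  idx <- time_index(epochs, time)
  e <- object$embed
  n_samp <- dim(epochs$data)[3L]
  if (idx - e < 1L || idx + e > n_samp) {
    stop("time too close to the epoch edge for the temporal embedding")
  }
  Xe <- embed_window(epochs$data, idx, e)
  Z <- apply_scale(sweep(Xe, 2L, object$center) %*% object$rotation,
                   object$scale)
  eta <- sweep(Z %*% object$coefs[-1L, , drop = FALSE], 2L,
               object$coefs[1L, ], "+")
  p <- stats::plogis(eta)
  p <- p / rowSums(p)
  colnames(p) <- object$states
  list(prob = p, label = object$states[apply(p, 1L, which.max)])
}

#' Per-state reactivation probabilities over a trial epoch
#'
#' Applies the one-versus-rest state classifiers at every usable time
#' point in a trial epoch (sliding the temporal embedding along the
#' trial), yielding the probability of each state being reactivated at
#' each time point. The first and last \code{embed} samples are trimmed by
#' the embedding, so a 6-s epoch at 100 Hz yields 590 rows.
#'
#' @param classifiers A \code{\link{train_state_classifiers}} object.
#' @param epoch A channels x samples matrix, or a
#'   \code{\link{sensor_epochs}} with the trial selected via \code{trial}.
#' @param trial Trial index when \code{epoch} is a \code{sensor_epochs}.
#' @return A time x states matrix of reactivation probabilities (rows sum
#'   to 1), with the corresponding sample times in the \code{"times"}
#'   attribute.
#' @export
reactivation_timecourse <- function(classifiers, epoch, trial = 1L) {
  if (inherits(epoch, "sensor_epochs")) {
    times <- epoch$times
    epoch <- epoch$data[trial, , , drop = TRUE]
  } else {
    times <- NULL
  }
  n_ch <- nrow(epoch); n_samp <- ncol(epoch)
  e <- classifiers$embed
  if (n_samp < 2L * e + 1L) stop("epoch shorter than the embedding window")
  use <- (e + 1L):(n_samp - e)
  offs <- (-e):e
  Xe <- matrix(NA_real_, length(use), n_ch * length(offs))
  for (o in seq_along(offs)) {
    Xe[, ((o - 1L) * n_ch + 1L):(o * n_ch)] <- t(epoch[, use + offs[o]])
  }
  Z <- apply_scale(sweep(Xe, 2L, classifiers$center) %*% classifiers$rotation,
                   classifiers$scale)
  eta <- sweep(Z %*% classifiers$coefs[-1L, , drop = FALSE], 2L,
               classifiers$coefs[1L, ], "+")
  p <- stats::plogis(eta)
  p <- p / rowSums(p)
  colnames(p) <- classifiers$states
  attr(p, "times") <- if (!is.null(times)) times[use] else use
  p
}

#' Mean reactivation probability within a cluster mask
#'
#' Reduces the per-trial probabilistic predictions of
#' \code{\link{temporal_generalization}} to one scalar per trial: the mean
#' predicted probability of the chosen state over the masked
#' (training time x task time) cells, the region of interest typically
#' taken from clusters showing significant reactivation.
#'
#' @param accuracy_map An \code{accuracy_map} from
#'   \code{\link{temporal_generalization}} (its \code{"prob_chosen"}
#'   attribute is used), or a trials x train x task array.
#' @param mask Logical matrix [train x task].
#' @return Numeric vector, one reactivation strength per trial.
#' @export
reactivation_strength <- function(accuracy_map, mask) {
  prob <- if (is.array(accuracy_map) && length(dim(accuracy_map)) == 3L) {
    accuracy_map
  } else {
    attr(accuracy_map, "prob_chosen")
  }
  if (is.null(prob)) stop("no probabilistic predictions available")
  mask <- as.logical(mask)
  if (!any(mask)) stop("mask must select at least one cell")
  dim(mask) <- dim(prob)[2:3]
  apply(prob, 1L, function(m) mean(m[mask]))
}

# connected-component labelling (4-connectivity) of a logical matrix
label_clusters <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      while (length(stack) > 0L) {
        cell <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        ci <- cell[1L]; cj <- cell[2L]
        if (ci < 1L || cj < 1L || ci > nrow(mask) || cj > ncol(mask)) next
        if (!mask[ci, cj] || lab[ci, cj] != 0L) next
        lab[ci, cj] <- cur
        stack <- c(stack, list(c(ci - 1L, cj), c(ci + 1L, cj),
                               c(ci, cj - 1L), c(ci, cj + 1L)))
      }
    }
  }
  lab
}

#' Cluster-based permutation test on 2D accuracy or correlation maps
#'
#' Thresholds pointwise statistics (one-sample t against a reference
#' value, or across-participant correlation with a covariate) at p < 0.05
#' (two-sided), groups suprathreshold cells into 4-connected clusters, and
#' assesses each cluster's mass against a max-cluster-mass null
#' distribution built by participant-level sign flipping (t) or covariate
#' permutation (correlation).
#'
#' @param maps List of per-participant matrices (equal dimensions), e.g.
#'   temporal-generalization accuracy maps.
#' @param comparator Either a single number (the chance level for a
#'   one-sample test, e.g. 0.5) or a numeric vector with one value per
#'   participant (a covariate for the correlation test, e.g. the
#'   generalization parameter G).
#' @param n_perm Number of permutations (>= 100; default 5000).
#' @param threshold_p Pointwise two-sided cluster-forming threshold
#'   (default 0.05).
#' @param seed Integer seed.
#' @return A list with \code{stat} (the pointwise statistic map),
#'   \code{clusters} (data frame: id, sign, mass, n_cells, p) and
#'   \code{cluster_map} (integer matrix labelling each cell's cluster, 0
#'   for none).
#' @export
cluster_test_map <- function(maps, comparator, n_perm = 5000L,
                             threshold_p = 0.05, seed = 1L) {
  P <- length(maps)
  if (P < 8L) stop("need at least 8 participants")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  dims <- dim(maps[[1L]])
  A <- vapply(maps, function(m) as.numeric(m), numeric(prod(dims)))
  if (all(apply(A, 1L, stats::sd) == 0)) {
    stop("degenerate input: maps are identical across participants")
  }
  is_corr <- length(comparator) > 1L
  if (is_corr && length(comparator) != P) {
    stop("covariate length must equal the number of participants")
  }
  df <- P - 2L + !is_corr  # P-1 for one-sample t, P-2 for correlation
  t_crit <- stats::qt(1 - threshold_p / 2, df)

  stat_fun <- if (is_corr) {
    cov_c <- comparator - mean(comparator)
    function(Ap, ord) {
      x <- cov_c[ord]
      xs <- sqrt(sum(x^2))
      Ac <- Ap - rowMeans(Ap)
      r <- (Ac %*% x) / (sqrt(rowSums(Ac^2)) * xs)
      r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
      r * sqrt(df / (1 - r^2))
    }
  } else {
    function(Dp, signs) {
      Ds <- sweep(Dp, 2L, signs, "*")
      m <- rowMeans(Ds)
      v <- (SS / P - m^2) * P / df
      se <- sqrt(v / P)
      se[se == 0] <- Inf
      m / se
    }
  }

  if (is_corr) {
    t_obs <- stat_fun(A, seq_len(P))
  } else {
    D <- A - comparator
    SS <- rowSums(D^2)
    t_obs <- stat_fun(D, rep(1, P))
  }
  t_obs[!is.finite(t_obs)] <- 0
  tmap <- matrix(t_obs, dims[1L], dims[2L])

  cluster_masses <- function(tm) {
    out <- list()
    for (sgn in c(1, -1)) {
      lab <- label_clusters(sgn * tm > t_crit)
      if (max(lab) > 0L) {
        for (cl in seq_len(max(lab))) {
          cells <- lab == cl
          out[[length(out) + 1L]] <- list(sign = sgn,
                                          mass = sum(abs(tm[cells])),
                                          n_cells = sum(cells),
                                          cells = cells)
        }
      }
    }
    out
  }

  obs <- cluster_masses(tmap)
  null_max <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    tm <- if (is_corr) {
      matrix(stat_fun(A, sample.int(P)), dims[1L], dims[2L])
    } else {
      matrix(stat_fun(D, sample(c(-1, 1), P, replace = TRUE)),
             dims[1L], dims[2L])
    }
    tm[!is.finite(tm)] <- 0
    cl <- cluster_masses(tm)
    if (length(cl) == 0L) 0 else max(vapply(cl, `[[`, numeric(1), "mass"))
  }, numeric(1)))

  cluster_map <- matrix(0L, dims[1L], dims[2L])
  res <- data.frame(id = integer(), sign = numeric(), mass = numeric(),
                    n_cells = integer(), p = numeric())
  for (k in seq_along(obs)) {
    cl <- obs[[k]]
    cluster_map[cl$cells] <- k
    res <- rbind(res, data.frame(
      id = k, sign = cl$sign, mass = cl$mass, n_cells = cl$n_cells,
      p = (1 + sum(null_max >= cl$mass)) / (n_perm + 1)
    ))
  }
  list(stat = tmap, clusters = res, cluster_map = cluster_map)
}
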