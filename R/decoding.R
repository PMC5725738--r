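# mean EEG over a sliding window [t_onset, t_onset + window_ms), trials x channels
window_mean <- function(epochs, t_onset, window_ms = 55) {
  sel <- epochs$times >= t_onset & epochs$times < t_onset + window_ms
  if (!any(sel)) stop("window [", t_onset, ", ", t_onset + window_ms,
                      ") ms contains no samples")
  x <- epochs$data[, , sel, drop = FALSE]
  apply(x, c(1, 2), mean)
}

# Ledoit-Wolf-style analytic shrinkage intensity toward nu * I for centered
# data rows z_k (class-centered); returns gamma in [0, 1]
lw_shrinkage <- function(Z) {
  n <- nrow(Z)
  S <- crossprod(Z) / n
  nu <- mean(diag(S))
  target <- diag(nu, ncol(Z))
  num <- 0
  for (k in seq_len(n)) {
    zk <- Z[k, ]
    num <- num + sum((tcrossprod(zk) - S)^2)
  }
  num <- num / n^2
  den <- sum((S - target)^2)
  if (den <= 0) return(0)
  min(1, max(0, num / den))
}

#' Train a regularized linear discriminant at one time window
#'
#' Averages the EEG within a 55 ms window aligned to `t_onset`, and fits a
#' shrinkage-regularized linear discriminant between the two rate classes:
#' \deqn{w \propto \hat\Sigma^{-1}(m_1 - m_0), \qquad
#'   \hat\Sigma = (1-\gamma) S + \gamma\,\nu I,}
#' where S is the pooled within-class covariance and \eqn{\nu} the mean of
#' its diagonal. The offset `c` centres the discriminant output at the class
#' midpoint. Intended training set: congruent audio-visual trials only, with
#' equal-rate (11 Hz) trials excluded.
#'
#' @param epochs An `epoched_eeg` object.
#' @param labels Binary class labels (1 = rate above the standard), one per
#'   trial; NA rows are dropped.
#' @param t_onset Window onset in ms.
#' @param window_ms Window length (default 55).
#' @param shrinkage `"lw"` for analytic (Ledoit-Wolf-style) shrinkage, or a
#'   fixed numeric intensity in \[0, 1\].
#' @return Object of class `discriminant_model`: `w`, `c`, `t_onset`,
#'   `window_ms`, `gamma`, `channels`.
#' @export
train_discriminant <- function(epochs, labels, t_onset, window_ms = 55,
                               shrinkage = "lw") {
  keep <- !is.na(labels)
  X <- window_mean(epochs, t_onset, window_ms)[keep, , drop = FALSE]
  y <- labels[keep]
  if (length(unique(y)) != 2) stop("both classes must be present")
  m0 <- colMeans(X[y == 0, , drop = FALSE])
  m1 <- colMeans(X[y == 1, , drop = FALSE])
  Z <- rbind(sweep(X[y == 0, , drop = FALSE], 2, m0),
             sweep(X[y == 1, , drop = FALSE], 2, m1))
  S <- crossprod(Z) / nrow(Z)
  gamma <- if (identical(shrinkage, "lw")) lw_shrinkage(Z) else {
    stopifnot(is.numeric(shrinkage), shrinkage >= 0, shrinkage <= 1)
    shrinkage
  }
  nu <- mean(diag(S))
  Sigma <- (1 - gamma) * S + gamma * nu * diag(ncol(X))
  w <- tryCatch(solve(Sigma, m1 - m0), error = function(e) {
    stop("covariance is rank-deficient; use shrinkage > 0")
  })
  structure(list(w = drop(w), c = -sum(w * (m0 + m1) / 2),
                 t_onset = t_onset, window_ms = window_ms, gamma = gamma,
                 channels = epochs$channels),
            class = "discriminant_model")
}

#' Apply discriminant models across time
#'
#' Computes the single-trial discriminant output `Y(t) = w(t) x(t) + c(t)`
#' for every trial of `epochs`, using, at each time point, the model trained
#' at that same time point.
#'
#' @param models List of `discriminant_model` objects (one per time point).
#' @param epochs `epoched_eeg` to score (any condition).
#' @return Object of class `discriminant_output`: `y` (trials x time),
#'   `times` (window onsets, ms), `trial_id`.
#' @export
apply_discriminant <- function(models, epochs) {
  if (inherits(models, "discriminant_model")) models <- list(models)
  y <- vapply(models, function(m) {
    if (!identical(m$channels, epochs$channels)) {
      stop("channel sets of model and epochs do not match")
    }
    drop(window_mean(epochs, m$t_onset, m$window_ms) %*% m$w) + m$c
  }, numeric(dim(epochs$data)[1]))
  y <- matrix(y, nrow = dim(epochs$data)[1])
  structure(list(y = y,
                 times = vapply(models, `[[`, numeric(1), "t_onset"),
                 trial_id = epochs$trial_id),
            class = "discriminant_output")
}

#' Sliding-window decoder training over a time grid
#'
#' Trains one discriminant per window onset on the training trials
#' (congruent audio-visual, equal-rate excluded) and returns the model list.
#'
#' @inheritParams train_discriminant
#' @param times Window-onset grid in ms (default `seq(25, 600, 5)`).
#' @return List of `discriminant_model`s.
#' @export
train_decoder <- function(epochs, labels, times = seq(25, 600, 5),
                          window_ms = 55, shrinkage = "lw") {
  lapply(times, function(t) {
    train_discriminant(epochs, labels, t, window_ms, shrinkage)
  })
}

# CV Az of the discriminant at one window
cv_az_at_t <- function(X, y, k = 10, shrinkage = "lw") {
  fold <- stratified_folds(y, k)
  scores <- rep(NA_real_, length(y))
  for (f in unique(fold)) {
    tr <- fold != f
    m0 <- colMeans(X[tr & y == 0, , drop = FALSE])
    m1 <- colMeans(X[tr & y == 1, , drop = FALSE])
    Z <- rbind(sweep(X[tr & y == 0, , drop = FALSE], 2, m0),
               sweep(X[tr & y == 1, , drop = FALSE], 2, m1))
    S <- crossprod(Z) / nrow(Z)
    gamma <- if (identical(shrinkage, "lw")) lw_shrinkage(Z) else shrinkage
    Sigma <- (1 - gamma) * S + gamma * mean(diag(S)) * diag(ncol(X))
    w <- solve(Sigma, m1 - m0)
    scores[!tr] <- drop(X[!tr, , drop = FALSE] %*% w)
  }
  roc_area(scores, y)
}

#' Cross-validated decoder Az with a max-statistic significance threshold
#'
#' Computes the 10-fold cross-validated ROC area of the rate decoder at each
#' window onset, plus a family-wise significance threshold from a label
#' permutation null: labels are shuffled `n_perm` times, the CV Az series is
#' recomputed, and the threshold is the (1 - alpha) quantile of the maximal
#' Az over time.
#'
#' @inheritParams train_decoder
#' @param k CV folds (default 10).
#' @param n_perm Label shuffles for the null (default 2000).
#' @param alpha Significance level (default 0.01).
#' @return List: `az` (tibble time_ms, az), `threshold`, `null_max`,
#'   `params`.
#' @export
decoder_az <- function(epochs, labels, times = seq(25, 600, 5),
                       window_ms = 55, k = 10, shrinkage = "lw",
                       n_perm = 2000, alpha = 0.01) {
  if (n_perm < 100) warning("n_perm < 100: unstable significance threshold")
  keep <- !is.na(labels)
  y <- labels[keep]
  tab <- table(y)
  if (max(tab) / min(tab) > 4) {
    message("classes unbalanced beyond 4:1; stratified folds enforced")
  }
  Xs <- lapply(times, function(t) {
    window_mean(epochs, t, window_ms)[keep, , drop = FALSE]
  })
  az_series <- function(yy) {
    vapply(Xs, cv_az_at_t, numeric(1), y = yy, k = k, shrinkage = shrinkage)
  }
  az_obs <- az_series(y)
  thr <- max_stat_threshold(function() az_series(sample(y)),
                            n_perm = n_perm, alpha = alpha)
  list(az = tibble::tibble(time_ms = times, az = az_obs),
       threshold = thr$threshold, null_max = thr$null_max,
       params = list(k = k, n_perm = n_perm, alpha = alpha,
                     window_ms = window_ms))
}

#' Forward-model scalp map of the discriminant component
#'
#' The per-channel, per-time normalized correlation (Pearson, across
#' trials) between the discriminant output and the window-averaged EEG: the
#' interpretable activation topography of the decoded component.
#'
#' @param y A `discriminant_output`.
#' @param epochs The `epoched_eeg` the output was computed from (same
#'   trials).
#' @param window_ms Window length used by the models (default 55).
#' @return Matrix channels x time with values in \[-1, 1\]; zero-variance
#'   channels yield NA.
#' @export
forward_model <- function(y, epochs, window_ms = 55) {
  if (nrow(y$y) != dim(epochs$data)[1]) {
    stop("discriminant output and epochs must hold the same trials")
  }
  a <- matrix(NA_real_, dim(epochs$data)[2], length(y$times),
              dimnames = list(epochs$channels, y$times))
  for (j in seq_along(y$times)) {
    X <- window_mean(epochs, y$times[j], window_ms)
    sds <- apply(X, 2, stats::sd)
    ok <- sds > 0 & stats::sd(y$y[, j]) > 0
    a[ok, j] <- suppressWarnings(stats::cor(y$y[, j], X[, ok]))
  }
  a
}

#' Rate class labels for decoder training
#'
#' Class 1 for experimental rates above the standard, 0 below, NA at the
#' standard rate (equal-rate trials carry no high/low label) and NA for
#' trials outside the training set (non-congruent or non-AV when
#' `congruent_only`).
#'
#' @param trials Trial table.
#' @param standard_rate Standard rate (default 11).
#' @param congruent_only Restrict labels to congruent AV trials (default
#'   TRUE, the decoder's training convention).
#' @return Integer vector of labels with NA for excluded trials.
#' @export
rate_labels <- function(trials, standard_rate = 11, congruent_only = TRUE) {
  lab <- ifelse(trials$rate > standard_rate, 1L,
                ifelse(trials$rate < standard_rate, 0L, NA_integer_))
  if (congruent_only) {
    lab[!(trials$modality == "AV" & !is.na(trials$delta) &
            trials$delta == 0)] <- NA_integer_
  }
  lab
}
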