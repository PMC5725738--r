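# accumulated-rate design matrices --------------------------------------

#' Accumulated-rate matrices for a trial table
#'
#' Builds trials x time matrices of accumulated auditory and visual event
#' counts on a time grid in ms (each grid value must align with the 12 ms
#' stimulus bin for the behavioural grid; arbitrary grids are allowed and
#' evaluated as "events with onset strictly before t").
#'
#' @param trials Trial table with `onsets_aud` / `onsets_vis` list-columns.
#' @param times Numeric time grid in ms.
#' @return List with matrices `acc_aud`, `acc_vis` (trials x time) and
#'   `times`.
#' @export
accumulated_matrices <- function(trials, times) {
  acc_of <- function(onsets) {
    if (is.null(onsets)) return(rep(NA_real_, length(times)))
    vapply(times, function(t) sum(onsets < t), numeric(1))
  }
  acc_aud <- t(vapply(trials$onsets_aud, acc_of, numeric(length(times))))
  acc_vis <- t(vapply(trials$onsets_vis, acc_of, numeric(length(times))))
  list(acc_aud = acc_aud, acc_vis = acc_vis, times = times)
}

# ridge-stabilized logistic regression (IRLS); ridge excludes the intercept
ridge_logistic <- function(X, y, ridge = 1e-6, max_iter = 100, tol = 1e-8) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  R <- diag(c(0, rep(ridge, p - 1)), p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(Xd * w)
    beta_new <- tryCatch(
      solve(XtW %*% Xd + R, XtW %*% z),
      error = function(e) NULL)
    if (is.null(beta_new)) return(NULL)
    beta_new <- drop(beta_new)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  beta
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(NULL)
  (x - mean(x)) / s
}

# fit choice ~ accA + accV at one time point; returns betas or NULL if the
# design is singular (constant or collinear accumulated counts)
fit_weights_at_t <- function(acc_a, acc_v, choice, ridge = 1e-6) {
  za <- zscore(acc_a); zv <- zscore(acc_v)
  if (is.null(za) || is.null(zv)) return(NULL)
  if (abs(stats::cor(za, zv)) > 0.999) return(NULL)
  beta <- ridge_logistic(cbind(za, zv), choice, ridge = ridge)
  if (is.null(beta)) return(NULL)
  c(beta_aud = unname(beta[2]), beta_vis = unname(beta[3]))
}

#' Time-resolved perceptual weights from accumulated evidence
#'
#' For each reliability condition and time point, regresses the behavioural
#' choice on the z-scored accumulated auditory and visual event counts with
#' a logistic model (intercept included; a tiny L2 ridge stabilizes
#' near-collinear late time points). Restricted to incongruent (delta = +-2)
#' audio-visual trials. Reported per time point: the raw coefficients and,
#' when both are positive, the normalized auditory/visual weights
#' `beta / (beta_aud + beta_vis)`.
#'
#' @param trials Trial table with `choice`; non-AV and congruent trials are
#'   dropped automatically.
#' @param window Analysis window in ms (default c(24, 600)).
#' @param step Grid step in ms (default 12).
#' @param ridge L2 stabilizer (default 1e-6).
#' @return Tibble: `subject_id`, `reliability`, `time_ms`, `beta_aud`,
#'   `beta_vis`, `w_aud`, `w_vis`, `normalized` (logical), `singular`
#'   (logical; TRUE rows carry NA estimates).
#' @export
time_resolved_weights <- function(trials, window = c(24, 600), step = 12,
                                  ridge = 1e-6) {
  av <- trials[trials$modality == "AV" & !is.na(trials$delta) &
                 trials$delta != 0, ]
  if (nrow(av) == 0) stop("no incongruent audio-visual trials")
  if (!all(c("high", "low") %in% av$reliability)) {
    stop("both reliability conditions must be present")
  }
  times <- seq(window[1], window[2], by = step)
  sid <- unique(av$subject_id)[1]
  purrr::map_dfr(c("high", "low"), function(rel) {
    sub <- av[av$reliability == rel, ]
    acc <- accumulated_matrices(sub, times)
    purrr::map_dfr(seq_along(times), function(j) {
      b <- fit_weights_at_t(acc$acc_aud[, j], acc$acc_vis[, j],
                            sub$choice, ridge)
      if (is.null(b)) {
        return(tibble::tibble(subject_id = sid, reliability = rel,
                              time_ms = times[j], beta_aud = NA_real_,
                              beta_vis = NA_real_, w_aud = NA_real_,
                              w_vis = NA_real_, normalized = FALSE,
                              singular = TRUE))
      }
      both_pos <- b[1] > 0 && b[2] > 0
      w_a <- if (both_pos) b[1] / (b[1] + b[2]) else b[1]
      w_v <- if (both_pos) b[2] / (b[1] + b[2]) else b[2]
      tibble::tibble(subject_id = sid, reliability = rel,
                     time_ms = times[j], beta_aud = unname(b[1]),
                     beta_vis = unname(b[2]), w_aud = w_a, w_vis = w_v,
                     normalized = both_pos, singular = FALSE)
    })
  })
}

# ROC area via the rank-sum (Mann-Whitney) identity
roc_area <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified k-fold assignment; guarantees both classes in every fold when
# feasible, re-stratifying by class
stratified_folds <- function(y, k) {
  if (min(table(y)) < k) {
    k <- max(2, min(table(y)))
  }
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  if (any(vapply(seq_len(k), function(f) length(unique(y[fold == f])) < 2,
                 logical(1)))) {
    stop("cannot build folds with both classes present")
  }
  fold
}

#' Cross-validated ROC area of the evidence model at one time point
#'
#' Stratified 10-fold cross-validation of the logistic
#' choice ~ accumulated-rate model; held-out predicted probabilities are
#' pooled across folds and scored with the area under the ROC curve (Az),
#' computed through the rank-sum identity `Az = U / (n1 * n0)`.
#'
#' @param acc_a,acc_v Accumulated auditory / visual counts at the time
#'   point (one value per trial).
#' @param choice Binary choices.
#' @param k Number of folds (default 10).
#' @param ridge L2 stabilizer.
#' @return Az in \[0, 1\] (NA if the design is singular).
#' @export
model_az <- function(acc_a, acc_v, choice, k = 10, ridge = 1e-6) {
  za <- zscore(acc_a); zv <- zscore(acc_v)
  if (is.null(za) || is.null(zv)) return(NA_real_)
  X <- cbind(za, zv)
  fold <- stratified_folds(choice, k)
  scores <- rep(NA_real_, length(choice))
  for (f in unique(fold)) {
    tr <- fold != f
    beta <- ridge_logistic(X[tr, , drop = FALSE], choice[tr], ridge)
    if (is.null(beta)) return(NA_real_)
    scores[!tr] <- drop(cbind(1, X[!tr, , drop = FALSE]) %*% beta)
  }
  roc_area(scores, choice)
}

#' Az time course of the evidence model
#'
#' Applies [model_az()] along the behavioural time grid for the incongruent
#' audio-visual trials of one subject (both reliabilities pooled).
#'
#' @inheritParams time_resolved_weights
#' @param k Folds for cross-validation.
#' @return Tibble: `subject_id`, `time_ms`, `az`.
#' @export
perceptual_az <- function(trials, window = c(24, 600), step = 12, k = 10,
                          ridge = 1e-6) {
  av <- trials[trials$modality == "AV" & !is.na(trials$delta) &
                 trials$delta != 0, ]
  times <- seq(window[1], window[2], by = step)
  acc <- accumulated_matrices(av, times)
  tibble::tibble(
    subject_id = unique(av$subject_id)[1],
    time_ms = times,
    az = vapply(seq_along(times), function(j) {
      model_az(acc$acc_aud[, j], acc$acc_vis[, j], av$choice, k, ridge)
    }, numeric(1)))
}

#' Reliability influence D(t)
#'
#' The difference of (auditory - visual) weights between the high- and
#' low-visual-reliability conditions at each time point:
#' \deqn{D(t) = [W_{AUD} - W_{VIS}]_{AVH} - [W_{AUD} - W_{VIS}]_{AVL}.}
#' NA weights propagate to NA.
#'
#' @param ws Weight tibble as returned by [time_resolved_weights()] or
#'   [neural_weight_regression()] (columns `subject_id`, `reliability`,
#'   `time_ms`, and the value columns named by `aud`/`vis`).
#' @param aud,vis Names of the auditory / visual value columns (default the
#'   normalized-or-raw `w_aud` / `w_vis`).
#' @return Tibble: `subject_id`, `time_ms`, `d`.
#' @export
reliability_influence <- function(ws, aud = "w_aud", vis = "w_vis") {
  need <- c("subject_id", "reliability", "time_ms", aud, vis)
  if (!all(need %in% names(ws))) {
    stop("weight tibble must have columns ", paste(need, collapse = ", "))
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(ws, dplyr::all_of(c("subject_id", "reliability",
                                      "time_ms", aud, vis))),
    names_from = "reliability", values_from = dplyr::all_of(c(aud, vis)))
  a_h <- wide[[paste0(aud, "_high")]]; v_h <- wide[[paste0(vis, "_high")]]
  a_l <- wide[[paste0(aud, "_low")]];  v_l <- wide[[paste0(vis, "_low")]]
  tibble::tibble(subject_id = wide$subject_id, time_ms = wide$time_ms,
                 d = (a_h - v_h) - (a_l - v_l))
}

#' Correlate a reliability-influence series with per-subject scalars
#'
#' Across-subject Spearman correlation at each time point between a
#' time-resolved reliability influence (e.g. from the regression weights)
#' and a per-subject scalar influence (e.g. from the psychometric weights).
#'
#' @param d_series Tibble from [reliability_influence()] over several
#'   subjects.
#' @param d_scalar Tibble with `subject_id` and `d` (one row per subject).
#' @return Tibble: `time_ms`, `rho`, `p`, `n`.
#' @export
weight_correlation <- function(d_series, d_scalar) {
  subjects <- intersect(unique(d_series$subject_id), d_scalar$subject_id)
  if (length(subjects) < 5) stop("need at least 5 common subjects")
  d_series <- d_series[d_series$subject_id %in% subjects, ]
  sc <- d_scalar$d[match(subjects, d_scalar$subject_id)]
  purrr::map_dfr(sort(unique(d_series$time_ms)), function(t) {
    dt <- d_series[d_series$time_ms == t, ]
    x <- dt$d[match(subjects, dt$subject_id)]
    ok <- stats::complete.cases(x, sc)
    if (sum(ok) < 5) {
      return(tibble::tibble(time_ms = t, rho = NA_real_, p = NA_real_,
                            n = sum(ok)))
    }
    s <- spearman(x[ok], sc[ok])
    tibble::tibble(time_ms = t, rho = s$rho, p = s$p, n = s$n)
  })
}
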