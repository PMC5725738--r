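#' Neural sensory weights by regression of the discriminant output
#'
#' For each reliability condition and each time point of the discriminant
#' output, regresses Y on the z-scored accumulated auditory and visual
#' event counts (ordinary least squares, intercept included). Restricted to
#' incongruent (delta = +-2) audio-visual trials; Y rows and trial-table
#' rows are aligned by `trial_id`. The four resulting series (auditory /
#' visual x high / low reliability) are deliberately left unnormalized.
#' Collinear or constant predictors at early time points yield flagged NA
#' rows; an ill-conditioned design (condition number > 1e6) falls back to a
#' small ridge.
#'
#' @param y A `discriminant_output`.
#' @param trials Trial table with onset list-columns (all trials; filtered
#'   internally).
#' @param window Analysis window in ms over the neural grid (default
#'   c(24, 400)).
#' @param ridge Fallback ridge for ill-conditioned designs.
#' @return Tibble: `subject_id`, `reliability`, `time_ms`, `b_aud`,
#'   `b_vis`, `singular`.
#' @export
neural_weight_regression <- function(y, trials, window = c(24, 400),
                                     ridge = 1e-6) {
  av <- trials[trials$modality == "AV" & !is.na(trials$delta) &
                 trials$delta != 0, ]
  if (nrow(av) == 0) stop("no incongruent audio-visual trials")
  rows <- match(av$trial_id, y$trial_id)
  if (any(is.na(rows))) stop("trial ids of Y and trial table do not align")
  tsel <- which(y$times >= window[1] & y$times <= window[2])
  times <- y$times[tsel]
  sid <- unique(av$subject_id)[1]
  purrr::map_dfr(c("high", "low"), function(rel) {
    idx <- av$reliability == rel
    sub <- av[idx, ]
    acc <- accumulated_matrices(sub, times)
    ysub <- y$y[rows[idx], tsel, drop = FALSE]
    purrr::map_dfr(seq_along(times), function(j) {
      za <- zscore(acc$acc_aud[, j]); zv <- zscore(acc$acc_vis[, j])
      bad <- is.null(za) || is.null(zv) || abs(stats::cor(za, zv)) > 0.999
      if (bad) {
        return(tibble::tibble(subject_id = sid, reliability = rel,
                              time_ms = times[j], b_aud = NA_real_,
                              b_vis = NA_real_, singular = TRUE))
      }
      X <- cbind(1, za, zv)
      XtX <- crossprod(X)
      kappa_x <- kappa(XtX, exact = TRUE)
      if (kappa_x > 1e6) XtX <- XtX + diag(c(0, ridge, ridge))
      b <- unname(drop(solve(XtX, crossprod(X, ysub[, j]))))
      tibble::tibble(subject_id = sid, reliability = rel,
                     time_ms = times[j], b_aud = b[2], b_vis = b[3],
                     singular = FALSE)
    })
  })
}

#' Reliability influence of the neural weights
#'
#' [reliability_influence()] applied to the unnormalized neural regression
#' coefficients.
#'
#' @param nw Tibble from [neural_weight_regression()].
#' @return Tibble: `subject_id`, `time_ms`, `d`.
#' @export
neural_reliability_influence <- function(nw) {
  reliability_influence(nw, aud = "b_aud", vis = "b_vis")
}

#' Neuro-behavioural correlation of reliability influences
#'
#' Across-subject Spearman correlation, at each time point, between the
#' neural and the perceptual reliability-influence series, with cluster
#' correction over time via the max-size permutation test. The perceptual
#' series is aligned to the neural time grid by nearest-neighbour
#' resampling.
#'
#' @param d_neural,d_perceptual Tibbles from the reliability-influence
#'   functions (`subject_id`, `time_ms`, `d`), for a common subject set.
#' @param t_threshold,min_size,n_perm Cluster-test parameters (see
#'   [cluster_permutation_cor()]).
#' @return List: `correlation` (tibble time_ms, rho, p, n) and `clusters`
#'   (a `cluster_result`).
#' @export
neuro_behavioral_correlation <- function(d_neural, d_perceptual,
                                         t_threshold = 1.8, min_size = 2,
                                         n_perm = 1000) {
  subjects <- intersect(unique(d_neural$subject_id),
                        unique(d_perceptual$subject_id))
  if (length(subjects) < 5) stop("need at least 5 common subjects")
  tn <- sort(unique(d_neural$time_ms))
  tp <- sort(unique(d_perceptual$time_ms))
  d_mat <- function(d, times_use, times_have) {
    nn <- vapply(times_use, function(t) {
      times_have[which.min(abs(times_have - t))]
    }, numeric(1))
    m <- matrix(NA_real_, length(subjects), length(times_use))
    for (i in seq_along(subjects)) {
      di <- d[d$subject_id == subjects[i], ]
      m[i, ] <- di$d[match(nn, di$time_ms)]
    }
    m
  }
  mn <- d_mat(d_neural, tn, tn)
  mp <- d_mat(d_perceptual, tn, tp)   # perceptual resampled to neural grid
  corr <- purrr::map_dfr(seq_along(tn), function(j) {
    ok <- stats::complete.cases(mn[, j], mp[, j])
    if (sum(ok) < 5) {
      return(tibble::tibble(time_ms = tn[j], rho = NA_real_, p = NA_real_,
                            n = sum(ok)))
    }
    s <- spearman(mn[ok, j], mp[ok, j])
    tibble::tibble(time_ms = tn[j], rho = s$rho, p = s$p, n = s$n)
  })
  cl <- cluster_permutation_cor(mn, mp, times = tn,
                                t_threshold = t_threshold,
                                min_size = min_size, n_perm = n_perm)
  list(correlation = corr, clusters = cl)
}
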