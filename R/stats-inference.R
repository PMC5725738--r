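#' Wilcoxon signed-rank test with Z-based effect size
#'
#' Paired two-sided Wilcoxon signed-rank test. The test statistic is
#' converted to a normal-approximation Z (with tie and zero corrections),
#' and the effect size is \eqn{r = Z/\sqrt{N}}, where N counts observations.
#' For small samples without ties, an exact p-value from the signed-rank
#' distribution is used.
#'
#' @param x,y Paired numeric vectors.
#' @param exact Use the exact signed-rank null when there are no ties/zeros
#'   and n <= 50 (default TRUE).
#' @return A tibble with `z`, `p`, `r`, `n` (pairs with nonzero difference),
#'   and `method`.
#' @examples
#' wilcoxon_effect(rnorm(12), rnorm(12))
#' @export
wilcoxon_effect <- function(x, y, exact = TRUE) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  n_obs <- length(d)
  if (n_obs < 5) stop("need at least 5 paired observations")
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0) {
    return(tibble::tibble(z = NA_real_, p = NA_real_, r = NA_real_,
                          n = 0L, method = "all ties (undefined)"))
  }
  r_abs <- rank(abs(nz))
  v <- sum(r_abs[nz > 0])
  mu_v <- n * (n + 1) / 4
  ties <- table(r_abs)
  sigma_v <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(ties^3 - ties) / 48)
  z <- (v - mu_v) / sigma_v
  has_ties <- any(duplicated(abs(nz))) || length(nz) < n_obs
  if (exact && !has_ties && n <= 50) {
    p <- min(1, 2 * min(stats::psignrank(v, n),
                        stats::psignrank(v - 1, n, lower.tail = FALSE)))
    method <- "exact signed-rank"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  tibble::tibble(z = z, p = p, r = z / sqrt(n_obs), n = n,
                 method = method)
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank tie handling and a two-sided p-value.
#' Constant input is flagged rather than erroring so that time-resolved
#' correlation series can carry degenerate time points as NA.
#'
#' @param x,y Numeric vectors of equal length, n >= 5.
#' @return Tibble with `rho`, `p`, `n`, `degenerate`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n,
                          degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = n,
                 degenerate = FALSE)
}

# one-sample t statistic per column of a subjects x time difference matrix
colwise_t <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  s <- apply(d, 2, stats::sd)
  t <- m / (s / sqrt(n))
  t[s == 0] <- 0
  t
}

# contiguous supra-threshold runs of one sign; returns start/end indices and size
find_clusters <- function(t_series, t_threshold, min_size) {
  supra_pos <- t_series > t_threshold
  supra_neg <- t_series < -t_threshold
  runs_of <- function(mask, sign) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_size
    if (!any(keep)) return(NULL)
    tibble::tibble(start = starts[keep], end = ends[keep],
                   size = r$lengths[keep], sign = sign)
  }
  out <- dplyr::bind_rows(runs_of(supra_pos, 1L), runs_of(supra_neg, -1L))
  if (is.null(out) || nrow(out) == 0) return(NULL)
  dplyr::arrange(out, .data$start)
}

#' Cluster-based permutation test for paired time series
#'
#' Compares two paired subjects-by-time series with the cluster-based
#' permutation method: a paired t statistic at each time point, contiguous
#' runs with |t| above a fixed threshold (default 1.8) and length at least
#' `min_size` (default 2) form clusters, the cluster statistic is the
#' cluster size (number of supra-threshold points), and the null is the
#' permutation distribution of the maximum cluster size under random
#' within-subject condition flips (sign flips of the paired differences).
#' Positive and negative runs are clustered separately against the common
#' max-size null (two-sided test). p-values carry the +1 correction and are
#' never exactly zero.
#'
#' @param a,b Matrices (subjects x time), same shape; `b` may be NULL if `a`
#'   already holds paired differences (test against zero).
#' @param times Optional time axis (ms) for reporting cluster spans.
#' @param t_threshold Cluster-forming threshold on |t| (default 1.8).
#' @param min_size Minimum cluster length in time points (default 2).
#' @param n_perm Number of sign-flip permutations (default 1000).
#' @return An object of class `cluster_result`: list with `clusters`
#'   (tibble: t_start, t_end, size, cluster_stat, p_value, sign), `t_series`,
#'   `times`, and the test parameters.
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(20 * 30), 20)
#' b <- matrix(rnorm(20 * 30), 20)
#' cluster_permutation(a, b, n_perm = 200)
#' @export
cluster_permutation <- function(a, b = NULL, times = NULL, t_threshold = 1.8,
                                min_size = 2, n_perm = 1000) {
  a <- as.matrix(a)
  d <- if (is.null(b)) a else a - as.matrix(b)
  if (!is.null(b) && !all(dim(a) == dim(as.matrix(b)))) {
    stop("`a` and `b` must have identical shape")
  }
  n_sub <- nrow(d); n_time <- ncol(d)
  if (n_sub < 5) stop("need at least 5 subjects")
  if (is.null(times)) times <- seq_len(n_time)
  t_obs <- colwise_t(d)
  obs <- find_clusters(t_obs, t_threshold, min_size)
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), n_sub, replace = TRUE)
    t_p <- colwise_t(d * flips)
    cl <- find_clusters(t_p, t_threshold, min_size)
    null_max[p] <- if (is.null(cl)) 0 else max(cl$size)
  }
  clusters <- if (is.null(obs)) {
    tibble::tibble(t_start = numeric(0), t_end = numeric(0),
                   size = integer(0), cluster_stat = numeric(0),
                   p_value = numeric(0), sign = integer(0))
  } else {
    tibble::tibble(
      t_start = times[obs$start], t_end = times[obs$end],
      size = obs$size, cluster_stat = as.numeric(obs$size),
      p_value = (1 + vapply(obs$size, function(s) sum(null_max >= s),
                            numeric(1))) / (1 + n_perm),
      sign = obs$sign)
  }
  structure(list(clusters = clusters, t_series = t_obs, times = times,
                 params = list(t_threshold = t_threshold, min_size = min_size,
                               n_perm = n_perm, statistic = "max-size",
                               tail = "two-sided"),
                 null_max = null_max),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$clusters), " cluster(s); |t| > ",
      x$params$t_threshold, ", min size ", x$params$min_size, ", ",
      x$params$n_perm, " permutations\n", sep = "")
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' @rdname cluster_permutation
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' Cluster-based permutation test for a correlation time course
#'
#' Tests, at each time point, the across-subject Spearman correlation of a
#' per-subject time series against a per-subject covariate (a scalar per
#' subject, or a second series on the same grid), and corrects over time
#' with the same max-size cluster permutation machinery as
#' [cluster_permutation()]. The cluster-forming statistic is the t-transform
#' of rho; the null permutes the subject assignment of the covariate.
#'
#' @param series Matrix subjects x time.
#' @param covariate Numeric vector (one value per subject) or matrix with
#'   the same shape as `series`.
#' @inheritParams cluster_permutation
#' @return A `cluster_result` whose extra field `rho` holds the observed
#'   correlation series.
#' @export
cluster_permutation_cor <- function(series, covariate, times = NULL,
                                    t_threshold = 1.8, min_size = 2,
                                    n_perm = 1000) {
  series <- as.matrix(series)
  n_sub <- nrow(series); n_time <- ncol(series)
  if (n_sub < 5) stop("need at least 5 subjects")
  cov_mat <- if (is.matrix(covariate)) covariate else
    matrix(covariate, n_sub, n_time)
  if (!all(dim(cov_mat) == dim(series))) stop("covariate shape mismatch")
  if (is.null(times)) times <- seq_len(n_time)
  rho_t <- function(s, cv) {
    vapply(seq_len(ncol(s)), function(j) {
      x <- s[, j]; y <- cv[, j]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 5 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        return(NA_real_)
      }
      r <- stats::cor(x[ok], y[ok], method = "spearman")
      n <- sum(ok)
      r * sqrt((n - 2) / max(1 - r^2, 1e-12))
    }, numeric(1))
  }
  t_obs <- rho_t(series, cov_mat)
  t_obs[is.na(t_obs)] <- 0
  obs <- find_clusters(t_obs, t_threshold, min_size)
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    idx <- sample.int(n_sub)
    t_p <- rho_t(series, cov_mat[idx, , drop = FALSE])
    t_p[is.na(t_p)] <- 0
    cl <- find_clusters(t_p, t_threshold, min_size)
    null_max[p] <- if (is.null(cl)) 0 else max(cl$size)
  }
  clusters <- if (is.null(obs)) {
    tibble::tibble(t_start = numeric(0), t_end = numeric(0),
                   size = integer(0), cluster_stat = numeric(0),
                   p_value = numeric(0), sign = integer(0))
  } else {
    tibble::tibble(
      t_start = times[obs$start], t_end = times[obs$end],
      size = obs$size, cluster_stat = as.numeric(obs$size),
      p_value = (1 + vapply(obs$size, function(s) sum(null_max >= s),
                            numeric(1))) / (1 + n_perm),
      sign = obs$sign)
  }
  structure(list(clusters = clusters, t_series = t_obs, times = times,
                 params = list(t_threshold = t_threshold, min_size = min_size,
                               n_perm = n_perm, statistic = "max-size",
                               tail = "two-sided"),
                 null_max = null_max),
            class = "cluster_result")
}

#' Max-statistic permutation threshold
#'
#' Family-wise multiple-comparison correction over a time course: a
#' user-supplied shuffler regenerates the statistic series under the null,
#' and the threshold is the (1 - alpha) quantile of the null distribution of
#' the maximum statistic over time.
#'
#' @param shuffler Function of no arguments returning one null statistic
#'   series (numeric vector) per call.
#' @param n_perm Number of permutations (default 2000).
#' @param alpha Significance level (default 0.01).
#' @return List with `threshold`, `null_max` (length `n_perm`), `alpha`,
#'   `n_perm`.
#' @export
max_stat_threshold <- function(shuffler, n_perm = 2000, alpha = 0.01) {
  if (n_perm * alpha < 5) {
    warning("n_perm * alpha < 5: the null quantile is unstable")
  }
  null_max <- vapply(seq_len(n_perm), function(i) max(shuffler(), na.rm = TRUE),
                     numeric(1))
  # ceil((1 - alpha) (n + 1))-th order statistic: the classical permutation
  # threshold whose exceedance probability under the null is at most alpha
  # (an interpolated quantile can be slightly anti-conservative)
  k <- min(n_perm, ceiling((1 - alpha) * (n_perm + 1)))
  list(threshold = sort(null_max)[k],
       null_max = null_max, alpha = alpha, n_perm = n_perm)
}
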