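test_that("wilcoxon effect size follows r = Z / sqrt(N)", {
  set.seed(31)
  x <- rnorm(40, 0.4); y <- rnorm(40)
  res <- wilcoxon_effect(x, y)
  expect_equal(res$r, res$z / sqrt(40))
  # the published pairing convention: a Z of -2.688 over 40 observations
  expect_equal(round(-2.688 / sqrt(40), 3), -0.425)
})

test_that("identical samples give Z = 0 and a flagged undefined test", {
  x <- rnorm(10)
  res <- wilcoxon_effect(x, x)
  expect_true(is.na(res$z))
  expect_match(res$method, "ties")
})

test_that("small-sample exact p matches full enumeration of sign patterns", {
  set.seed(32)
  d <- c(0.8, -0.3, 1.2, 0.5, -0.9, 1.7)
  res <- wilcoxon_effect(d + 5, rep(5, 6))
  # enumerate all 2^6 sign assignments of the ranked |d|
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  v_null <- as.matrix(signs) %*% r
  p_exact <- mean(abs(v_null - 10.5) >= abs(v_obs - 10.5))
  expect_equal(res$p, p_exact, tolerance = 1e-12)
})

test_that("spearman matches Pearson-on-ranks and handles monotone maps", {
  set.seed(33)
  x <- rnorm(30)
  expect_equal(spearman(x, x^3)$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  # ties-containing data against the definition oracle
  a <- sample(1:5, 40, replace = TRUE)
  b <- a + sample(0:2, 40, replace = TRUE)
  expect_equal(spearman(a, b)$rho, cor(rank(a), rank(b)))
  expect_true(spearman(rep(1, 10), rnorm(10))$degenerate)
})

test_that("equal conditions produce no clusters", {
  set.seed(34)
  a <- matrix(rnorm(200), 10)
  res <- cluster_permutation(a, a, n_perm = 100)
  expect_equal(nrow(res$clusters), 0)
})

test_that("cluster permutation p matches exhaustive sign-flip enumeration", {
  set.seed(35)
  n_sub <- 8; n_time <- 15
  d <- matrix(rnorm(n_sub * n_time), n_sub)
  d[, 5:9] <- d[, 5:9] + 1.1          # ensures an observed cluster
  res <- cluster_permutation(d, n_perm = 2000, t_threshold = 1.8,
                             min_size = 2)
  expect_gt(nrow(res$clusters), 0)
  # exact null: all 2^8 sign assignments
  t_of <- function(m) {
    s <- apply(m, 2, sd); tt <- colMeans(m) / (s / sqrt(nrow(m)))
    tt[s == 0] <- 0; tt
  }
  max_size_of <- function(tt) {
    best <- 0
    for (sgn in c(1, -1)) {
      r <- rle(sgn * tt > 1.8)
      sizes <- r$lengths[r$values & r$lengths >= 2]
      if (length(sizes)) best <- max(best, max(sizes))
    }
    best
  }
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_sub)))
  null_max <- apply(flips, 1, function(f) max_size_of(t_of(d * f)))
  for (i in seq_len(nrow(res$clusters))) {
    p_exact <- mean(null_max >= res$clusters$size[i])
    mc_se <- sqrt(p_exact * (1 - p_exact) / 2000) + 1 / 2000
    expect_lt(abs(res$clusters$p_value[i] - p_exact), 4 * mc_se + 0.005)
  }
})

test_that("a strong contiguous effect is detected with small p", {
  set.seed(36)
  a <- matrix(rnorm(20 * 40), 20)
  a[, 11:20] <- a[, 11:20] + 2
  res <- cluster_permutation(a, matrix(rnorm(20 * 40), 20), n_perm = 1000)
  big <- res$clusters[which.max(res$clusters$size), ]
  expect_gte(big$size, 8)
  expect_gte(big$t_start, 8); expect_lte(big$t_end, 23)
  expect_lte(big$p_value, 0.005)
})

test_that("permutation p-values are never zero and runs are deterministic", {
  set.seed(37)
  a <- matrix(rnorm(160, 2), 8)
  r1 <- cluster_permutation(a, n_perm = 200)
  expect_true(all(r1$clusters$p_value > 0))
  expect_true(all(r1$clusters$p_value >= 1 / 201))
  set.seed(37)
  r2 <- cluster_permutation(a, n_perm = 200)
  expect_identical(r1$clusters, r2$clusters)
})

test_that("max-statistic threshold is a null-max order statistic, monotone in alpha", {
  set.seed(38)
  shuffler <- function() abs(rnorm(30))
  set.seed(39)
  t01 <- max_stat_threshold(shuffler, n_perm = 1000, alpha = 0.01)
  set.seed(39)
  t05 <- max_stat_threshold(shuffler, n_perm = 1000, alpha = 0.05)
  expect_gte(t01$threshold, t05$threshold)
  # the ceil((1 - alpha)(n + 1))-th order statistic of the null maxima
  expect_equal(t01$threshold, sort(t01$null_max)[ceiling(0.99 * 1001)])
  expect_equal(t05$threshold, sort(t05$null_max)[ceiling(0.95 * 1001)])
  expect_warning(max_stat_threshold(shuffler, n_perm = 100, alpha = 0.01),
                 "unstable")
})

test_that("cluster and max-statistic corrections control family-wise error", {
  set.seed(40)
  n_datasets <- 200
  fp_cluster <- 0
  for (i in seq_len(n_datasets)) {
    d <- matrix(rnorm(12 * 30), 12)
    res <- cluster_permutation(d, n_perm = 100)
    if (any(res$clusters$p_value < 0.05)) fp_cluster <- fp_cluster + 1
  }
  # binomial 95% upper bound around nominal 0.05 with 200 draws
  expect_lte(fp_cluster / n_datasets, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200))

  fp_max <- 0
  for (i in seq_len(n_datasets)) {
    series <- abs(rnorm(25))
    thr <- max_stat_threshold(function() abs(rnorm(25)), n_perm = 200,
                              alpha = 0.05)
    if (any(series > thr$threshold)) fp_max <- fp_max + 1
  }
  expect_lte(fp_max / n_datasets, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200))
})

test_that("correlation clusters appear for coupled data and not for noise", {
  set.seed(41)
  n_sub <- 20; n_time <- 30
  subj <- rnorm(n_sub)
  series <- outer(subj, c(rep(0, 10), rep(1, 10), rep(0, 10))) +
    matrix(rnorm(n_sub * n_time, sd = 0.4), n_sub)
  res <- cluster_permutation_cor(series, subj, n_perm = 500)
  expect_gt(nrow(res$clusters), 0)
  sig <- res$clusters[res$clusters$p_value < 0.05, ]
  expect_gt(nrow(sig), 0)
  expect_true(any(sig$t_start >= 10 & sig$t_end <= 21))

  null_series <- matrix(rnorm(n_sub * n_time), n_sub)
  res0 <- cluster_permutation_cor(null_series, rnorm(n_sub), n_perm = 300)
  expect_true(all(res0$clusters$p_value > 0.01))
})
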