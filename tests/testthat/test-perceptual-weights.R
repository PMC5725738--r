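test_that("logistic coefficients are recovered with orthogonal evidence", {
  set.seed(61)
  n <- 5000
  za <- rnorm(n); zv <- rnorm(n)           # independent regressors
  beta_true <- c(aud = 1.2, vis = 0.6)
  p <- plogis(0.1 + beta_true["aud"] * za + beta_true["vis"] * zv)
  choice <- rbinom(n, 1, p)
  b <- avweights:::fit_weights_at_t(za, zv, choice)
  expect_lt(abs(b["beta_aud"] - beta_true["aud"]) / beta_true["aud"], 0.1)
  expect_lt(abs(b["beta_vis"] - beta_true["vis"]) / beta_true["vis"], 0.1)
})

test_that("coin-flip choices give near-zero weights and chance Az", {
  set.seed(62)
  tt <- toy_trials(900)
  tt$choice <- rbinom(nrow(tt), 1, 0.5)
  pw <- time_resolved_weights(tt)
  late <- pw[pw$time_ms >= 300 & !pw$singular, ]
  expect_lt(abs(mean(late$beta_aud)), 0.15)
  expect_lt(abs(mean(late$beta_vis)), 0.15)
  az <- perceptual_az(tt)
  expect_lt(abs(mean(az$az, na.rm = TRUE) - 0.5), 0.06)
})

test_that("weights reflect the observer's reliability-dependent bias", {
  set.seed(63)
  des <- default_design(510)
  des$n[des$modality == "AV" & des$delta %in% c(-2, 2)] <- 1500L
  obs <- observer_params(w_aud_true_high = 0.25, w_aud_true_low = 0.85)
  tt <- simulate_choices(generate_trial_table(des), obs)
  pw <- time_resolved_weights(tt)
  late <- pw[pw$time_ms >= 400 & !pw$singular, ]
  m <- tapply(late$w_aud, late$reliability, mean, na.rm = TRUE)
  expect_gt(m["low"], m["high"])  # auditory up-weighted when vision degraded
  d <- reliability_influence(pw)
  expect_lt(mean(d$d[d$time_ms >= 400], na.rm = TRUE), 0)
})

test_that("weights grow as evidence accumulates", {
  set.seed(64)
  des <- default_design(510)
  des$n[des$modality == "AV" & des$delta %in% c(-2, 2)] <- 1500L
  tt <- simulate_choices(generate_trial_table(des), observer_params())
  pw <- time_resolved_weights(tt)
  ok <- pw[!pw$singular & pw$reliability == "high", ]
  early <- mean(abs(ok$beta_aud[ok$time_ms <= 150]), na.rm = TRUE)
  late <- mean(abs(ok$beta_aud[ok$time_ms >= 450]), na.rm = TRUE)
  expect_gt(late, early)
})

test_that("singular designs are flagged, not fatal", {
  set.seed(65)
  # auditory and visual streams identical -> perfectly collinear evidence
  n <- 40
  streams <- purrr::map(rep(c(10, 12), n / 2),
                        function(r) generate_event_stream(r)$onsets)
  tt <- tibble::tibble(
    trial_id = seq_len(n), subject_id = "S01", modality = "AV",
    reliability = rep(c("high", "low"), each = n / 2),
    delta = rep(c(2, -2), n / 2), rate = 11, rate_aud = 11, rate_vis = 11,
    is_equal_rate = FALSE, onsets_aud = streams, onsets_vis = streams,
    choice = rbinom(n, 1, 0.5))
  pw <- time_resolved_weights(tt, window = c(24, 120))
  expect_true(all(pw$singular))
  expect_true(all(is.na(pw$w_aud)))
})

test_that("Az equals the Mann-Whitney U statistic over n1 n0", {
  set.seed(66)
  scores <- rnorm(200)
  labels <- rbinom(200, 1, 0.4)
  az <- avweights:::roc_area(scores, labels)
  w <- wilcox.test(scores[labels == 1], scores[labels == 0])
  expect_equal(az, unname(w$statistic) / (sum(labels == 1) * sum(labels == 0)))
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(az,
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
  }
})

test_that("cross-validated Az is near 1 for separable evidence", {
  set.seed(67)
  n <- 300
  acc_a <- rnorm(n); acc_v <- rnorm(n)
  choice <- as.integer(acc_a + acc_v > 0)
  expect_gt(model_az(acc_a, acc_v, choice), 0.95)
})

test_that("reliability influence is exact arithmetic with NaN propagation", {
  ws <- tidyr::expand_grid(subject_id = "S01", reliability = c("high", "low"),
                           time_ms = c(100, 200))
  ws$w_aud <- c(0.8, 0.8, 0.6, NA)   # high@100, high@200, low@100, low@200
  ws$w_vis <- 1 - ws$w_aud
  d <- reliability_influence(ws)
  expect_equal(d$d[d$time_ms == 100], (0.8 - 0.2) - (0.6 - 0.4))
  expect_true(is.na(d$d[d$time_ms == 200]))
  # identical conditions give exactly zero
  ws2 <- ws; ws2$w_aud <- 0.7; ws2$w_vis <- 0.3
  expect_equal(reliability_influence(ws2)$d, c(0, 0))
})

test_that("reliability influence matches a brute-force recomputation", {
  set.seed(68)
  grid <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:6),
                             reliability = c("high", "low"),
                             time_ms = seq(24, 120, 12))
  grid$w_aud <- runif(nrow(grid)); grid$w_vis <- runif(nrow(grid))
  d <- reliability_influence(grid)
  for (i in sample(nrow(d), 10)) {
    g <- grid[grid$subject_id == d$subject_id[i] &
                grid$time_ms == d$time_ms[i], ]
    manual <- (g$w_aud[g$reliability == "high"] - g$w_vis[g$reliability == "high"]) -
      (g$w_aud[g$reliability == "low"] - g$w_vis[g$reliability == "low"])
    expect_equal(d$d[i], manual)
  }
})

test_that("weight correlation is 1 for identical and monotone inputs", {
  set.seed(69)
  subs <- sprintf("S%02d", 1:10)
  d_scalar <- tibble::tibble(subject_id = subs, d = rnorm(10))
  d_series <- tidyr::expand_grid(subject_id = subs, time_ms = c(50, 100)) |>
    dplyr::left_join(d_scalar, by = "subject_id")
  res <- weight_correlation(d_series, d_scalar)
  expect_equal(res$rho, c(1, 1))
  # monotone transform leaves Spearman untouched
  d_series$d <- d_series$d^3
  expect_equal(weight_correlation(d_series, d_scalar)$rho, c(1, 1))
  # independent noise stays small for most runs
  set.seed(70)
  hits <- 0
  for (i in 1:50) {
    d_series$d <- rnorm(nrow(d_series))
    r <- weight_correlation(d_series, d_scalar)$rho[1]
    if (abs(r) < 0.55) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.9)
})
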