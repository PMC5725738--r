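test_that("unregularized weights match the analytic Fisher direction", {
  set.seed(71)
  n <- 400
  Sigma <- matrix(c(1, 0.6, 0.6, 2), 2)
  L <- chol(Sigma)
  mdiff <- c(1.5, -0.5)
  X0 <- matrix(rnorm(n * 2), n) %*% L
  X1 <- sweep(matrix(rnorm(n * 2), n) %*% L, 2, -mdiff)
  data <- array(0, c(2 * n, 2, 4))
  for (t in 1:4) data[, , t] <- rbind(X0, X1)
  ep <- structure(list(data = data, times = c(0, 5, 10, 15),
                       channels = c("CH01", "CH02"),
                       trial_id = seq_len(2 * n)), class = "epoched_eeg")
  labels <- rep(0:1, each = n)
  m <- train_discriminant(ep, labels, t_onset = 0, window_ms = 20,
                          shrinkage = 0)
  w_fisher <- solve(Sigma, colMeans(X1) - colMeans(X0))
  cosine <- sum(m$w * w_fisher) / sqrt(sum(m$w^2) * sum(w_fisher^2))
  expect_gt(cosine, 0.999)
})

test_that("full shrinkage reduces to the class-mean difference", {
  toy <- toy_epochs(n_trials = 80, n_ch = 3, seed = 72)
  m <- train_discriminant(toy$epochs, toy$labels, t_onset = 0,
                          window_ms = 100, shrinkage = 1)
  X <- avweights:::window_mean(toy$epochs, 0, 100)
  md <- colMeans(X[toy$labels == 1, ]) - colMeans(X[toy$labels == 0, ])
  # w proportional to m1 - m0 under the identity covariance limit
  expect_equal(m$w / sqrt(sum(m$w^2)), md / sqrt(sum(md^2)), tolerance = 1e-10)
})

test_that("regularized weights equal an explicit-inverse solve", {
  # brute-force oracle on a small problem, to numerical precision
  set.seed(73)
  toy <- toy_epochs(n_trials = 40, n_ch = 3, n_t = 8, seed = 73)
  for (gamma in c(0.2, 0.7)) {
    m <- train_discriminant(toy$epochs, toy$labels, t_onset = 0,
                            window_ms = 40, shrinkage = gamma)
    X <- avweights:::window_mean(toy$epochs, 0, 40)
    y <- toy$labels
    m0 <- colMeans(X[y == 0, ]); m1 <- colMeans(X[y == 1, ])
    Z <- rbind(sweep(X[y == 0, ], 2, m0), sweep(X[y == 1, ], 2, m1))
    S <- t(Z) %*% Z / nrow(Z)
    Sigma <- (1 - gamma) * S + gamma * mean(diag(S)) * diag(3)
    w_oracle <- solve(Sigma) %*% (m1 - m0)
    expect_equal(m$w, drop(w_oracle), tolerance = 1e-10)
    expect_equal(m$c, -sum(w_oracle * (m0 + m1) / 2), tolerance = 1e-10)
  }
})

test_that("rank-deficient covariance without shrinkage is an error", {
  toy <- toy_epochs(n_trials = 10, n_ch = 20, n_t = 4, seed = 74)
  expect_error(train_discriminant(toy$epochs, toy$labels, 0, 20,
                                  shrinkage = 0), "shrinkage")
})

test_that("applying a model reproduces training-time scores", {
  toy <- toy_epochs(seed = 75)
  m <- train_discriminant(toy$epochs, toy$labels, 0, 50)
  out <- apply_discriminant(list(m), toy$epochs)
  X <- avweights:::window_mean(toy$epochs, 0, 50)
  expect_equal(out$y[, 1], drop(X %*% m$w) + m$c)
  # scores separate classes in the right direction
  expect_gt(mean(out$y[toy$labels == 1, 1]), mean(out$y[toy$labels == 0, 1]))
})

test_that("channel mismatch is an error", {
  toy <- toy_epochs(seed = 76)
  m <- train_discriminant(toy$epochs, toy$labels, 0, 50)
  ep2 <- toy$epochs
  ep2$channels <- rev(ep2$channels)
  expect_error(apply_discriminant(list(m), ep2), "channel")
})

test_that("decoder Az is near chance on noise and high on signal", {
  set.seed(77)
  toy_null <- toy_epochs(n_trials = 120, n_ch = 6, n_t = 30, sep = 0,
                         seed = 77)
  daz <- suppressWarnings(
    decoder_az(toy_null$epochs, toy_null$labels,
               times = seq(0, 100, 25), window_ms = 30, n_perm = 0))
  expect_true(all(abs(daz$az$az - 0.5) < 0.15))
  toy_sig <- toy_epochs(n_trials = 120, n_ch = 6, n_t = 30, sep = 1.5,
                        seed = 78)
  daz2 <- suppressWarnings(
    decoder_az(toy_sig$epochs, toy_sig$labels,
               times = seq(0, 100, 25), window_ms = 30, n_perm = 0))
  expect_true(all(daz2$az$az > 0.9))
})

test_that("max-statistic null controls false positives on shuffled labels", {
  set.seed(79)
  hits <- 0; n_runs <- 60
  for (i in seq_len(n_runs)) {
    toy <- toy_epochs(n_trials = 40, n_ch = 3, n_t = 24, sep = 0, seed = 100 + i)
    daz <- suppressWarnings(
      decoder_az(toy$epochs, toy$labels, times = seq(0, 80, 20),
                 window_ms = 25, n_perm = 60, alpha = 0.05))
    if (any(daz$az$az > daz$threshold)) hits <- hits + 1
  }
  expect_lte(hits / n_runs, 0.05 + 2.5 * sqrt(0.05 * 0.95 / n_runs))
})

test_that("decoder thresholds are reproducible under a fixed seed", {
  toy <- toy_epochs(n_trials = 60, n_ch = 4, n_t = 20, seed = 80)
  set.seed(80)
  d1 <- suppressWarnings(decoder_az(toy$epochs, toy$labels,
                                    times = c(0, 25, 50), n_perm = 50,
                                    window_ms = 30))
  set.seed(80)
  d2 <- suppressWarnings(decoder_az(toy$epochs, toy$labels,
                                    times = c(0, 25, 50), n_perm = 50,
                                    window_ms = 30))
  expect_identical(d1$threshold, d2$threshold)
  expect_identical(d1$az, d2$az)
})

test_that("forward model recovers the generating mixing vector", {
  set.seed(81)
  # auditory-only signal buried in spatially white noise; the activation
  # map of the true source is proportional to the mixing vector
  tt <- simulate_choices(generate_trial_table(default_design(2000)))
  fwd_clean <- eeg_forward_params(n_channels = 12, noise_sd = 0,
                                  gain_aud = c(high = 1, low = 1),
                                  gain_vis = c(high = 0, low = 0))
  ep_clean <- simulate_eeg(tt, fwd_clean, fs = 100)
  set.seed(810)
  ep_noisy <- ep_clean
  ep_noisy$data <- ep_clean$data +
    array(rnorm(length(ep_clean$data)), dim(ep_clean$data))
  y_src <- drop(avweights:::window_mean(ep_clean, 250, 55) %*% fwd_clean$mix_aud)
  y <- structure(list(y = matrix(y_src, ncol = 1), times = 250,
                      trial_id = ep_noisy$trial_id),
                 class = "discriminant_output")
  a <- forward_model(y, ep_noisy)
  cosine <- sum(a[, 1] * fwd_clean$mix_aud) /
    sqrt(sum(a[, 1]^2) * sum(fwd_clean$mix_aud^2))
  expect_gt(cosine, 0.99)
  expect_true(all(abs(a) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("forward model is exact when Y equals a channel", {
  toy <- toy_epochs(n_trials = 50, n_ch = 4, n_t = 10, seed = 82)
  X <- avweights:::window_mean(toy$epochs, 0, 25)
  y <- structure(list(y = matrix(X[, 2], ncol = 1), times = 0,
                      trial_id = toy$epochs$trial_id),
                 class = "discriminant_output")
  a <- forward_model(y, toy$epochs, window_ms = 25)
  expect_equal(a[2, 1], 1)
})

test_that("rate labels exclude equal-rate and non-congruent trials", {
  set.seed(83)
  tt <- generate_trial_table(default_design(450), include_streams = FALSE)
  lab <- rate_labels(tt)
  expect_true(all(is.na(lab[tt$rate == 11])))
  expect_true(all(is.na(lab[tt$modality != "AV"])))
  expect_true(all(is.na(lab[tt$modality == "AV" & tt$delta != 0])))
  cong <- tt$modality == "AV" & tt$delta == 0 & tt$rate != 11
  cong[is.na(tt$delta)] <- FALSE
  expect_equal(lab[cong], as.integer(tt$rate[cong] > 11))
})
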