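# shared fixture builders; everything is generated in code at test time

# small trial table with simulated choices
toy_trials <- function(n = 270, obs = observer_params(), seed = 42) {
  set.seed(seed)
  simulate_choices(generate_trial_table(default_design(n)), obs)
}

# two-class Gaussian epochs with a known informative channel pattern:
# class means differ by `sep * pattern` at every sample
toy_epochs <- function(n_trials = 60, n_ch = 4, n_t = 20, sep = 2,
                       pattern = NULL, noise_sd = 1, fs = 200, seed = 1) {
  set.seed(seed)
  if (is.null(pattern)) pattern <- rep(1, n_ch) / sqrt(n_ch)
  labels <- rep(0:1, length.out = n_trials)
  data <- array(stats::rnorm(n_trials * n_ch * n_t, sd = noise_sd),
                dim = c(n_trials, n_ch, n_t))
  for (i in which(labels == 1)) {
    data[i, , ] <- data[i, , ] + sep * pattern
  }
  times <- seq(0, by = 1000 / fs, length.out = n_t)
  ep <- structure(list(data = data, times = times,
                       channels = sprintf("CH%02d", seq_len(n_ch)),
                       trial_id = seq_len(n_trials)),
                  class = "epoched_eeg")
  list(epochs = ep, labels = labels)
}

# brute-force accumulated count: naive per-bin rescan
naive_accumulated <- function(onsets, t_end, bin_ms = 12) {
  n_bins <- t_end %/% bin_ms
  out <- integer(n_bins)
  for (k in seq_len(n_bins)) {
    cnt <- 0L
    for (o in onsets) if (o < k * bin_ms) cnt <- cnt + 1L
    out[k] <- cnt
  }
  out
}
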