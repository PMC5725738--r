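#' Observer parameters for the synthetic noisy observer
#'
#' The generative observer forms noisy internal rate estimates with
#' modality- and reliability-dependent Gaussian noise (SDs in Hz), combines
#' them on audio-visual trials with a fixed auditory weight (allowing
#' suboptimal, biased observers), and reports "first stream higher" when the
#' combined estimate exceeds the standard rate, with a small lapse
#' probability. Defaults reproduce the study conditions: auditory threshold
#' 2.19 Hz, visual thresholds 2.87 (high) / 4.55 Hz (low reliability), and a
#' pronounced auditory bias (true auditory weights 0.80 / 0.84).
#'
#' @param sigma_aud Auditory sensory noise SD (Hz).
#' @param sigma_vis_high,sigma_vis_low Visual noise SDs by reliability.
#' @param w_aud_true_high,w_aud_true_low True auditory combination weights
#'   in \[0, 1\] on audio-visual trials.
#' @param lapse Lapse probability in \[0, 0.1\].
#' @param standard_rate Standard stream rate (Hz).
#' @return List of class `observer_params`.
#' @export
observer_params <- function(sigma_aud = 2.19, sigma_vis_high = 2.87,
                            sigma_vis_low = 4.55, w_aud_true_high = 0.80,
                            w_aud_true_low = 0.84, lapse = 0.01,
                            standard_rate = 11) {
  stopifnot(sigma_aud > 0, sigma_vis_high > 0, sigma_vis_low > 0,
            w_aud_true_high >= 0, w_aud_true_high <= 1,
            w_aud_true_low >= 0, w_aud_true_low <= 1,
            lapse >= 0, lapse <= 0.1)
  structure(list(sigma_aud = sigma_aud, sigma_vis_high = sigma_vis_high,
                 sigma_vis_low = sigma_vis_low,
                 w_aud_true_high = w_aud_true_high,
                 w_aud_true_low = w_aud_true_low, lapse = lapse,
                 standard_rate = standard_rate),
            class = "observer_params")
}

#' Simulate behavioural choices for a trial table
#'
#' Draws internal rate estimates `rhat_A ~ N(rate_aud, sigma_aud)` and
#' `rhat_V ~ N(rate_vis, sigma_vis(reliability))`, combines them as
#' `w * rhat_A + (1 - w) * rhat_V` on audio-visual trials (the unisensory
#' estimate otherwise), and reports 1 ("first stream higher") when the
#' estimate exceeds the standard rate, flipped with probability `lapse`.
#'
#' @param trials Trial table from [generate_trial_table()].
#' @param obs An [observer_params()] object.
#' @return The trial table with a `choice` column (0/1) added.
#' @export
simulate_choices <- function(trials, obs = observer_params()) {
  n <- nrow(trials)
  need_aud <- trials$modality %in% c("AUD", "AV")
  need_vis <- trials$modality %in% c("VIS", "AV")
  if (any(need_aud & is.na(trials$rate_aud)) ||
      any(need_vis & is.na(trials$rate_vis))) {
    stop("missing rates for presented modalities")
  }
  sigma_vis <- ifelse(trials$reliability == "high",
                      obs$sigma_vis_high, obs$sigma_vis_low)
  w <- ifelse(trials$reliability == "high",
              obs$w_aud_true_high, obs$w_aud_true_low)
  mean_a <- ifelse(is.na(trials$rate_aud), 0, trials$rate_aud)
  mean_v <- ifelse(is.na(trials$rate_vis), 0, trials$rate_vis)
  rhat_a <- stats::rnorm(n, mean_a, obs$sigma_aud)
  rhat_v <- stats::rnorm(n, mean_v, sigma_vis)
  est <- dplyr::case_when(
    trials$modality == "AUD" ~ rhat_a,
    trials$modality == "VIS" ~ rhat_v,
    TRUE ~ w * rhat_a + (1 - w) * rhat_v
  )
  choice <- as.integer(est > obs$standard_rate)
  flip <- stats::runif(n) < obs$lapse
  trials$choice <- ifelse(flip, 1L - choice, choice)
  trials
}

#' Forward-model parameters for the synthetic EEG generator
#'
#' The generator is a linear forward model: per trial, each modality's
#' event train is convolved with a causal gamma-shaped evoked kernel,
#' delayed by a modality-specific latency, scaled by a reliability-dependent
#' gain, and projected into channel space through a fixed unit-norm mixing
#' vector; spatially correlated Gaussian noise is added. It is an
#' artifact-side generative stand-in with known ground truth (gains,
#' latencies, mixing vectors), not a model of cortical dynamics. Default
#' latencies place visual rate information at 90 ms and auditory at 160 ms;
#' reducing visual reliability halves the visual gain and raises the
#' auditory gain.
#'
#' @param n_channels Number of channels (default 64).
#' @param mix_aud,mix_vis Unit-norm channel mixing vectors; by default fixed
#'   smooth topographies (deterministic, independent of the RNG).
#' @param gain_aud,gain_vis Named numeric `c(high =, low =)` gains.
#' @param latency_aud_ms,latency_vis_ms Response latencies (ms).
#' @param kernel_peak_ms,kernel_width_ms Gamma kernel mode and SD (ms).
#' @param noise_sd Channel noise SD (same units as the signal).
#' @param noise_spatial_scale Spatial correlation length in channel index
#'   units (exponential decay).
#' @return List of class `eeg_forward_params`.
#' @export
eeg_forward_params <- function(n_channels = 64,
                               mix_aud = NULL, mix_vis = NULL,
                               gain_aud = c(high = 1.0, low = 1.3),
                               gain_vis = c(high = 1.0, low = 0.5),
                               latency_aud_ms = 160, latency_vis_ms = 90,
                               kernel_peak_ms = 100, kernel_width_ms = 50,
                               noise_sd = 1, noise_spatial_scale = 4) {
  if (is.null(mix_aud)) {
    # smooth "fronto-central" bump over the channel axis
    mix_aud <- exp(-((seq_len(n_channels) - n_channels * 0.3)^2) /
                     (2 * (n_channels / 8)^2))
  }
  if (is.null(mix_vis)) {
    # smooth "occipital" bump
    mix_vis <- exp(-((seq_len(n_channels) - n_channels * 0.75)^2) /
                     (2 * (n_channels / 8)^2))
  }
  mix_aud <- mix_aud / sqrt(sum(mix_aud^2))
  mix_vis <- mix_vis / sqrt(sum(mix_vis^2))
  stopifnot(length(mix_aud) == n_channels, length(mix_vis) == n_channels,
            all(gain_aud >= 0), all(gain_vis >= 0),
            latency_aud_ms >= 0, latency_vis_ms >= 0, noise_sd >= 0)
  structure(list(n_channels = n_channels, mix_aud = mix_aud,
                 mix_vis = mix_vis, gain_aud = gain_aud, gain_vis = gain_vis,
                 latency_aud_ms = latency_aud_ms,
                 latency_vis_ms = latency_vis_ms,
                 kernel_peak_ms = kernel_peak_ms,
                 kernel_width_ms = kernel_width_ms,
                 noise_sd = noise_sd,
                 noise_spatial_scale = noise_spatial_scale),
            class = "eeg_forward_params")
}

# causal gamma pulse with mode `peak` and SD `width`, peak-normalized to 1
evoked_kernel <- function(t_ms, peak, width) {
  theta <- (-peak + sqrt(peak^2 + 4 * width^2)) / 2
  alpha <- peak / theta + 1
  k <- ifelse(t_ms <= 0, 0, stats::dgamma(t_ms, shape = alpha, scale = theta))
  kmax <- stats::dgamma(peak, shape = alpha, scale = theta)
  k / kmax
}

# source time course: event train convolved with kernel, delayed, scaled
source_trace <- function(onsets, times, gain, latency, peak, width) {
  if (is.null(onsets) || length(onsets) == 0 || gain == 0) {
    return(numeric(length(times)))
  }
  s <- numeric(length(times))
  for (o in onsets) s <- s + evoked_kernel(times - o - latency, peak, width)
  gain * s
}

#' Simulate epoched EEG for a trial table
#'
#' Applies the linear forward model of [eeg_forward_params()] to every
#' trial's event streams and returns an `epoched_eeg` container (array
#' trials x channels x time with channel labels and a time axis in ms,
#' aligned to stream onset).
#'
#' @param trials Trial table (rows define trials; onset list-columns are
#'   used).
#' @param fwd An [eeg_forward_params()] object.
#' @param fs Sampling rate in Hz (default 200).
#' @param epoch_window Epoch span in ms relative to stream onset
#'   (default c(-200, 800)); the pre-stimulus segment is pure noise.
#' @return Object of class `epoched_eeg`: list with `data`
#'   (trials x channels x time), `times` (ms), `channels`, `trial_id`.
#' @export
simulate_eeg <- function(trials, fwd = eeg_forward_params(), fs = 200,
                         epoch_window = c(-200, 800)) {
  step <- 1000 / fs
  times <- seq(epoch_window[1], epoch_window[2], by = step)
  min_span <- max(fwd$latency_aud_ms, fwd$latency_vis_ms) + fwd$kernel_peak_ms
  if (epoch_window[2] < min_span) {
    stop("epoch window ends at ", epoch_window[2], " ms but latency + kernel",
         " peak needs at least ", min_span, " ms")
  }
  n_trials <- nrow(trials); n_ch <- fwd$n_channels; n_t <- length(times)
  # spatial noise covariance: exponential decay over the channel axis
  L <- if (fwd$noise_sd > 0) {
    idx <- seq_len(n_ch)
    chol(exp(-abs(outer(idx, idx, "-")) / fwd$noise_spatial_scale))
  } else NULL
  data <- array(0, dim = c(n_trials, n_ch, n_t))
  for (i in seq_len(n_trials)) {
    rel <- trials$reliability[i]
    s_aud <- source_trace(trials$onsets_aud[[i]], times,
                          fwd$gain_aud[[rel]], fwd$latency_aud_ms,
                          fwd$kernel_peak_ms, fwd$kernel_width_ms)
    s_vis <- source_trace(trials$onsets_vis[[i]], times,
                          fwd$gain_vis[[rel]], fwd$latency_vis_ms,
                          fwd$kernel_peak_ms, fwd$kernel_width_ms)
    x <- outer(fwd$mix_aud, s_aud) + outer(fwd$mix_vis, s_vis)
    if (!is.null(L)) {
      x <- x + fwd$noise_sd * crossprod(L, matrix(stats::rnorm(n_ch * n_t),
                                                  n_ch, n_t))
    }
    data[i, , ] <- x
  }
  structure(list(data = data, times = times,
                 channels = sprintf("CH%02d", seq_len(n_ch)),
                 trial_id = trials$trial_id),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoched_eeg> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples (", min(x$times), "..", max(x$times), " ms)\n", sep = "")
  invisible(x)
}

#' Draw per-subject generator parameters
#'
#' Produces heterogeneous observers and forward models for a simulated
#' group. Each subject's true low-reliability auditory weight deviates from
#' the group mean by a subject effect `u` applied on the log-odds scale
#' (keeping weights inside (0, 1) without truncation; some subjects shift
#' opposite to the reliability prediction, as real groups do). When
#' `coupled = TRUE`, the standardized effect `u / sd_w` also scales the
#' reliability dependence of the neural gains, so behavioural and neural
#' reliability effects share a subject-level cause; when `FALSE`, the
#' neural gain perturbation uses an independent draw. The default spread
#' (`sd_w = 1.5` log-odds units) makes roughly half of the simulated
#' subjects shift opposite to the reliability prediction, matching the
#' heterogeneity of real groups, and together with the coupling strength
#' (`gain_slope = 1.8`, gain scale SD 0.45, floored at 0.2) yields an
#' attainable between-subject neuro-behavioural correlation of about 0.5
#' at the default session length.
#'
#' @param n_subjects Number of subjects.
#' @param obs_base,fwd_base Group-level parameter objects.
#' @param sd_w SD of the subject effect on the log-odds of the
#'   low-reliability auditory weight.
#' @param coupled Couple behavioural and neural subject effects?
#' @param gain_slope Scale of the subject effect on the low-reliability
#'   gains.
#' @return List of per-subject lists with elements `obs` and `fwd`.
#' @export
sample_subjects <- function(n_subjects, obs_base = observer_params(),
                            fwd_base = eeg_forward_params(), sd_w = 1.5,
                            coupled = TRUE, gain_slope = 1.8) {
  lapply(seq_len(n_subjects), function(i) {
    u <- stats::rnorm(1, 0, sd_w)
    u_neural <- if (coupled) u else stats::rnorm(1, 0, sd_w)
    obs <- obs_base
    obs$w_aud_true_low <- stats::plogis(stats::qlogis(obs$w_aud_true_low) + u)
    fwd <- fwd_base
    scale <- pmax(0.2, 1 + gain_slope * u_neural / max(sd_w, 1e-9) * 0.25)
    fwd$gain_aud[["low"]] <- fwd$gain_aud[["low"]] * scale
    fwd$gain_vis[["low"]] <- fwd$gain_vis[["low"]] / scale
    list(obs = obs, fwd = fwd)
  })
}

#' Write a complete synthetic study to disk
#'
#' Generates, per subject, a trial table with simulated choices (CSV with
#' JSON-encoded onset lists) and an epoched EEG container (RDS holding the
#' `epoched_eeg` list: data trials x channels x time, times, channels,
#' trial_id). Fully deterministic given `seed`; per-subject RNG substreams
#' are derived from it.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param trials_per_subject Trials per subject (default 510).
#' @param subjects Optional list from [sample_subjects()]; drawn with
#'   defaults if NULL.
#' @param seed Base seed.
#' @param dir Output directory (created if needed).
#' @param design_fn Function(n_trials) returning a design tibble.
#' @param fs,epoch_window Passed to [simulate_eeg()].
#' @param write_eeg Set FALSE to skip EEG simulation (behaviour-only study).
#' @return Tibble manifest: subject_id, trials_csv, epochs_rds.
#' @export
make_study <- function(n_subjects = 20, trials_per_subject = 510,
                       subjects = NULL, seed = 1, dir = tempfile("study"),
                       design_fn = default_design, fs = 200,
                       epoch_window = c(-200, 800), write_eeg = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(subjects)) {
    set.seed(seed %% 2147483647L)
    subjects <- sample_subjects(n_subjects)
  }
  stopifnot(length(subjects) == n_subjects)
  manifest <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    set.seed((seed + 7919L * i) %% 2147483647L)
    sid <- sprintf("S%02d", i)
    tt <- generate_trial_table(design_fn(trials_per_subject),
                               subject_id = sid)
    tt <- simulate_choices(tt, subjects[[i]]$obs)
    csv <- file.path(dir, paste0(sid, "_trials.csv"))
    write_trial_table(tt, csv)
    rds <- NA_character_
    if (write_eeg) {
      ep <- simulate_eeg(tt, subjects[[i]]$fwd, fs = fs,
                         epoch_window = epoch_window)
      rds <- file.path(dir, paste0(sid, "_epochs.rds"))
      saveRDS(ep, rds)
    }
    tibble::tibble(subject_id = sid, trials_csv = csv, epochs_rds = rds)
  })
  manifest
}
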