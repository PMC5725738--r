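#' Study configuration
#'
#' Collects every tunable of the simulation and analysis pipeline with
#' defaults mirroring the task design: 510 trials per block, rates 8-14 Hz
#' with the 11 Hz standard, 55 ms decoding windows on a 5 ms grid,
#' behavioural grid of 12 ms bins over 24-600 ms, neural-weight window
#' 24-400 ms, cluster threshold t = 1.8 with minimum size 2 and 1000
#' randomizations, and 2000 shuffles for the max-statistic Az threshold.
#'
#' @param seed Base seed for all randomness.
#' @param n_subjects,trials_per_subject Study size.
#' @param obs,fwd Group-level generator parameters.
#' @param coupled Couple behavioural and neural subject effects in
#'   [sample_subjects()].
#' @param fs,epoch_window EEG sampling rate (Hz) and epoch span (ms).
#' @param window_behav,step_behav Behavioural analysis grid (ms).
#' @param window_y,step_y Discriminant output grid (ms).
#' @param window_neural Neural-weight window (ms).
#' @param window_ms Decoder window length (ms).
#' @param t_threshold,min_size,n_perm_cluster Cluster-test parameters.
#' @param n_perm_max,alpha_max Max-statistic permutation parameters.
#' @param n_boot Bootstrap draws for psychometric fits.
#' @return List of class `study_config`.
#' @export
study_config <- function(seed = 1, n_subjects = 20, trials_per_subject = 510,
                         obs = observer_params(), fwd = eeg_forward_params(),
                         coupled = TRUE, fs = 200,
                         epoch_window = c(-200, 800),
                         window_behav = c(24, 600), step_behav = 12,
                         window_y = c(25, 600), step_y = 5,
                         window_neural = c(24, 400), window_ms = 55,
                         t_threshold = 1.8, min_size = 2,
                         n_perm_cluster = 1000, n_perm_max = 2000,
                         alpha_max = 0.01, n_boot = 200) {
  cfg <- as.list(environment())
  structure(cfg, class = "study_config")
}

#' Read / write a study configuration
#'
#' Serializes a configuration to YAML (or JSON when the path ends in
#' `.json`); parameter objects round-trip exactly.
#'
#' @param config A `study_config`.
#' @param path File path.
#' @return `write_config()` the path, invisibly; `read_config()` the
#'   restored `study_config`.
#' @export
write_config <- function(config, path) {
  as_map <- function(v) {
    # named atomic vectors must become maps, or YAML drops the names
    if (is.atomic(v) && !is.null(names(v))) as.list(v) else v
  }
  plain <- lapply(unclass(config), function(x) {
    if (inherits(x, c("observer_params", "eeg_forward_params"))) {
      lapply(unclass(x), as_map)
    } else {
      as_map(x)
    }
  })
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(plain, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  plain <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- study_config()
  for (nm in names(plain)) {
    x <- plain[[nm]]
    if (nm == "obs") x <- do.call(observer_params, x)
    if (nm == "fwd") {
      x <- lapply(x, function(v) if (is.list(v)) unlist(v) else v)
      x <- do.call(eeg_forward_params, x)
    }
    cfg[[nm]] <- x
  }
  cfg
}

#' Run the full simulation + analysis pipeline
#'
#' Executes the stages simulate -> psychfit -> pweights -> decode ->
#' nweights -> stats on a synthetic study and returns every intermediate
#' result. When `out_dir` is given, stage artifacts (CSV tables, the JSON
#' cluster report, and summary figures) are written there; the raw study
#' files land in `file.path(out_dir, "study")`.
#'
#' @param config A [study_config()].
#' @param out_dir Optional output directory.
#' @param keep_eeg Keep the simulated epochs in memory / on disk (set FALSE
#'   for behaviour-only runs).
#' @param verbose Print stage progress.
#' @return List with elements `config`, `psych` (per-subject fits and
#'   weights), `d_psych` (per-subject scalar reliability influence),
#'   `pweights`, `az_behav`, `d_percept`, `decoding` (per-subject az
#'   tibbles + threshold), `nweights`, `d_neural`, `stats` (cluster tests
#'   and the neuro-behavioural correlation).
#' @export
run_pipeline <- function(config = study_config(), out_dir = NULL,
                         keep_eeg = TRUE, verbose = interactive()) {
  say <- function(...) if (verbose) message(...)
  set.seed(config$seed %% 2147483647L)
  subjects <- sample_subjects(config$n_subjects, config$obs, config$fwd,
                              coupled = config$coupled)
  study_dir <- if (is.null(out_dir)) tempfile("study") else
    file.path(out_dir, "study")
  say("simulate: ", config$n_subjects, " subjects x ",
      config$trials_per_subject, " trials")
  manifest <- make_study(config$n_subjects, config$trials_per_subject,
                         subjects = subjects, seed = config$seed,
                         dir = study_dir, fs = config$fs,
                         epoch_window = config$epoch_window,
                         write_eeg = keep_eeg)

  say("psychfit: psychometric weights")
  psych <- purrr::map(manifest$trials_csv, function(f) {
    psychometric_weights(read_trial_table(f), n_boot = config$n_boot)
  })
  names(psych) <- manifest$subject_id
  weights_tbl <- purrr::imap_dfr(psych, function(p, sid) {
    dplyr::mutate(p$weights, subject_id = sid, .before = 1)
  })
  d_psych <- weights_tbl |>
    dplyr::mutate(d_part = 2 * .data$w_aud_obs - 1) |>
    dplyr::select("subject_id", "reliability", "d_part") |>
    tidyr::pivot_wider(names_from = "reliability", values_from = "d_part") |>
    dplyr::transmute(subject_id = .data$subject_id,
                     d = .data$high - .data$low)

  say("pweights: time-resolved perceptual weights")
  trials_all <- purrr::map(manifest$trials_csv, read_trial_table)
  pweights <- purrr::map_dfr(trials_all, time_resolved_weights,
                             window = config$window_behav,
                             step = config$step_behav)
  az_behav <- purrr::map_dfr(trials_all, perceptual_az,
                             window = config$window_behav,
                             step = config$step_behav)
  d_percept <- reliability_influence(pweights)

  decoding <- nweights <- d_neural <- NULL
  if (keep_eeg) {
    say("decode: sliding-window rLDA")
    times_y <- seq(config$window_y[1], config$window_y[2], config$step_y)
    per_subj <- purrr::map2(manifest$epochs_rds, trials_all, function(f, tt) {
      ep <- readRDS(f)
      lab <- rate_labels(tt)
      models <- train_decoder(ep, lab, times = times_y,
                              window_ms = config$window_ms)
      yout <- apply_discriminant(models, ep)
      list(y = yout, trials = tt, epochs_file = f, labels = lab)
    })
    say("nweights: regression of Y on accumulated rates")
    nweights <- purrr::map_dfr(per_subj, function(s) {
      neural_weight_regression(s$y, s$trials, window = config$window_neural)
    })
    d_neural <- neural_reliability_influence(nweights)
    decoding <- list(times = times_y)
  }

  say("stats: cluster permutations")
  stats_out <- list()
  wmat <- function(tbl, rel, col) {
    wide <- tbl[tbl$reliability == rel, c("subject_id", "time_ms", col)]
    tidyr::pivot_wider(wide, names_from = "time_ms",
                       values_from = dplyr::all_of(col)) |>
      dplyr::select(-"subject_id") |> as.matrix()
  }
  bt <- sort(unique(pweights$time_ms))
  stats_out$percept_aud_rel <- cluster_permutation(
    wmat(pweights, "high", "w_aud"), wmat(pweights, "low", "w_aud"),
    times = bt, t_threshold = config$t_threshold,
    min_size = config$min_size, n_perm = config$n_perm_cluster)
  stats_out$percept_vs_psych <- weight_correlation(d_percept, d_psych)
  if (keep_eeg) {
    nt <- sort(unique(nweights$time_ms))
    stats_out$neural_aud_rel <- cluster_permutation(
      wmat(nweights, "high", "b_aud"), wmat(nweights, "low", "b_aud"),
      times = nt, t_threshold = config$t_threshold,
      min_size = config$min_size, n_perm = config$n_perm_cluster)
    stats_out$neural_vis_rel <- cluster_permutation(
      wmat(nweights, "high", "b_vis"), wmat(nweights, "low", "b_vis"),
      times = nt, t_threshold = config$t_threshold,
      min_size = config$min_size, n_perm = config$n_perm_cluster)
    stats_out$neuro_behav <- neuro_behavioral_correlation(
      d_neural, d_percept, t_threshold = config$t_threshold,
      min_size = config$min_size, n_perm = config$n_perm_cluster)
  }

  out <- list(config = config, manifest = manifest, psych = psych,
              weights = weights_tbl, d_psych = d_psych,
              pweights = pweights, az_behav = az_behav,
              d_percept = d_percept, decoding = decoding,
              nweights = nweights, d_neural = d_neural, stats = stats_out)
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

# stage artifacts: CSV tables, JSON cluster report, figures
write_report <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$weights, file.path(out_dir, "psych_weights.csv"),
                   row.names = FALSE)
  utils::write.csv(res$pweights, file.path(out_dir, "perceptual_weights.csv"),
                   row.names = FALSE)
  utils::write.csv(res$az_behav, file.path(out_dir, "az_behaviour.csv"),
                   row.names = FALSE)
  if (!is.null(res$nweights)) {
    utils::write.csv(res$nweights, file.path(out_dir, "neural_weights.csv"),
                     row.names = FALSE)
  }
  cl_json <- lapply(res$stats, function(s) {
    if (inherits(s, "cluster_result")) {
      as.list(s$clusters)
    } else if (is.list(s) && !is.data.frame(s) &&
               inherits(s[["clusters"]], "cluster_result")) {
      as.list(s[["clusters"]]$clusters)
    } else {
      NULL
    }
  })
  jsonlite::write_json(cl_json[!vapply(cl_json, is.null, logical(1))],
                       file.path(out_dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in c("az_behav", "pweights")) {
    p <- if (nm == "az_behav") plot_az(res$az_behav) else
      plot_weight_series(res$pweights)
    try(ggplot2::ggsave(file.path(out_dir, paste0(nm, ".pdf")), p,
                        width = 7, height = 4), silent = TRUE)
  }
  invisible(out_dir)
}

# ---- plotting ---------------------------------------------------------

#' Plot an Az time course
#'
#' Group mean with a standard-error ribbon; an optional horizontal line
#' marks a max-statistic significance threshold.
#'
#' @param az Tibble with `subject_id`, `time_ms`, `az`.
#' @param threshold Optional significance threshold.
#' @return A ggplot.
#' @export
plot_az <- function(az, threshold = NULL) {
  sm <- az |>
    dplyr::group_by(.data$time_ms) |>
    dplyr::summarise(m = mean(.data$az, na.rm = TRUE),
                     se = stats::sd(.data$az, na.rm = TRUE) /
                       sqrt(sum(!is.na(.data$az))), .groups = "drop")
  p <- ggplot2::ggplot(sm, ggplot2::aes(.data$time_ms, .data$m)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$se,
                                      ymax = .data$m + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = "Time (ms)", y = "Az") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  }
  p
}

#' Plot weight time courses by modality and reliability
#'
#' @param ws Weight tibble ([time_resolved_weights()] or
#'   [neural_weight_regression()] output).
#' @param aud,vis Value columns to plot.
#' @return A ggplot.
#' @export
plot_weight_series <- function(ws, aud = intersect(c("w_aud", "b_aud"),
                                                   names(ws))[1],
                               vis = intersect(c("w_vis", "b_vis"),
                                               names(ws))[1]) {
  long <- ws |>
    dplyr::select("subject_id", "reliability", "time_ms",
                  dplyr::all_of(c(aud, vis))) |>
    tidyr::pivot_longer(dplyr::all_of(c(aud, vis)), names_to = "modality",
                        values_to = "weight") |>
    dplyr::mutate(modality = ifelse(grepl("aud", .data$modality),
                                    "auditory", "visual")) |>
    dplyr::group_by(.data$reliability, .data$modality, .data$time_ms) |>
    dplyr::summarise(m = mean(.data$weight, na.rm = TRUE),
                     se = stats::sd(.data$weight, na.rm = TRUE) /
                       sqrt(sum(!is.na(.data$weight))), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_ms, .data$m,
                                     colour = .data$modality,
                                     fill = .data$modality)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$se,
                                      ymax = .data$m + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~reliability) +
    ggplot2::labs(x = "Time (ms)", y = "Weight") +
    ggplot2::theme_minimal()
}

#' Plot a correlation time course with significant clusters
#'
#' @param corr Tibble with `time_ms`, `rho`.
#' @param clusters Optional `cluster_result`; clusters with p < alpha are
#'   shaded.
#' @param alpha Significance level for shading.
#' @return A ggplot.
#' @export
plot_correlation <- function(corr, clusters = NULL, alpha = 0.05) {
  p <- ggplot2::ggplot(corr, ggplot2::aes(.data$time_ms, .data$rho)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = "Spearman rho") +
    ggplot2::theme_minimal()
  if (!is.null(clusters)) {
    sig <- clusters$clusters[clusters$clusters$p_value < alpha, ]
    if (nrow(sig)) {
      p <- p + ggplot2::annotate("rect", xmin = sig$t_start,
                                 xmax = sig$t_end, ymin = -Inf, ymax = Inf,
                                 alpha = 0.15)
    }
  }
  p
}
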