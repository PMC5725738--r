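#' Generate a single event stream
#'
#' Builds one trial's stream of brief (12 ms) sensory events inside a 900 ms
#' window. Events are separated by pauses drawn from \{48, 96\} ms; the pause
#' arrangement is randomized uniformly over the feasible compositions by
#' rejection sampling, and any remaining time at the tail of the window is
#' silence. With probability 1/2 the stream starts with a leading pause
#' (drawn from the same set), otherwise the first event starts at 0 ms.
#'
#' @param rate Integer nominal event rate in Hz; the stream carries exactly
#'   `rate` events. Must lie in 8--14.
#' @param stream_dur_ms Total stream duration in ms (default 900).
#' @param event_dur_ms Event duration in ms (default 12).
#' @param pause_ms Allowed inter-event pause durations in ms.
#' @param lead_pause_prob Probability that the stream begins with a pause
#'   rather than an event at time 0.
#' @param max_reject Cap on rejection-sampling attempts.
#' @return An object of class `event_stream`: a list with `onsets` (ms),
#'   `event_dur_ms`, `rate`, and `stream_dur_ms`.
#' @examples
#' s <- generate_event_stream(11)
#' length(s$onsets) # 11
#' @export
generate_event_stream <- function(rate, stream_dur_ms = 900, event_dur_ms = 12,
                                  pause_ms = c(48, 96), lead_pause_prob = 0.5,
                                  max_reject = 10000) {
  if (length(rate) != 1L || is.na(rate) || rate != round(rate) ||
      rate < 8 || rate > 14) {
    stop("`rate` must be a single integer in 8..14 Hz, got ", rate)
  }
  n_events <- as.integer(rate)
  # minimal occupancy: all internal gaps at the shortest pause
  min_occ <- n_events * event_dur_ms + (n_events - 1L) * min(pause_ms)
  if (min_occ > stream_dur_ms) {
    stop("infeasible rate/duration combination: ", n_events, " events of ",
         event_dur_ms, " ms with minimum pauses of ", min(pause_ms),
         " ms occupy ", min_occ, " ms > ", stream_dur_ms, " ms window")
  }
  for (i in seq_len(max_reject)) {
    lead <- if (stats::runif(1) < lead_pause_prob) sample(pause_ms, 1L) else 0
    gaps <- if (n_events > 1L) sample(pause_ms, n_events - 1L, replace = TRUE) else numeric(0)
    onsets <- lead + cumsum(c(0, gaps + event_dur_ms))
    if (onsets[n_events] + event_dur_ms <= stream_dur_ms) {
      return(structure(
        list(onsets = onsets, event_dur_ms = event_dur_ms,
             rate = n_events, stream_dur_ms = stream_dur_ms),
        class = "event_stream"))
    }
  }
  stop("rejection sampling failed after ", max_reject,
       " attempts; no feasible pause composition found")
}

#' @export
print.event_stream <- function(x, ...) {
  cat("<event_stream> ", x$rate, " Hz, ", length(x$onsets), " events in ",
      x$stream_dur_ms, " ms\n", sep = "")
  invisible(x)
}

#' Accumulated event rate of a stream
#'
#' Counts, for each 12 ms time bin, the number of event onsets that occurred
#' strictly before the end of that bin. This cumulative event count is the
#' sensory-evidence regressor used by the time-resolved weight analyses; a
#' full 900 ms stream yields 75 time points.
#'
#' @param stream An `event_stream`, or a bare numeric vector of onset times
#'   in ms.
#' @param t_end End of the accumulation window in ms; must be a positive
#'   multiple of `bin_ms` and at most the stream duration.
#' @param bin_ms Bin width in ms (default 12, the event duration).
#' @return Integer vector of length `t_end / bin_ms`; element k is the event
#'   count accumulated up to `k * bin_ms` ms.
#' @examples
#' s <- generate_event_stream(11)
#' acc <- accumulated_rate(s)
#' acc[length(acc)] # == 11
#' @export
accumulated_rate <- function(stream, t_end = NULL, bin_ms = 12) {
  onsets <- if (inherits(stream, "event_stream")) stream$onsets else as.numeric(stream)
  dur <- if (inherits(stream, "event_stream")) stream$stream_dur_ms else NULL
  if (is.null(t_end)) t_end <- if (is.null(dur)) 900 else dur
  if (t_end <= 0 || t_end %% bin_ms != 0) {
    stop("`t_end` (", t_end, ") must be a positive multiple of the ",
         bin_ms, " ms bin grid")
  }
  if (!is.null(dur) && t_end > dur) stop("`t_end` exceeds stream duration")
  n_bins <- t_end %/% bin_ms
  edges <- bin_ms * seq_len(n_bins)
  vapply(edges, function(e) sum(onsets < e), integer(1))
}

# Per-condition rate allocation implementing the design's rate histogram.
# Congruent / unisensory conditions draw the experimental rate from 8..14;
# incongruent conditions draw the *average* rate from 9..13 so that both
# component rates stay within 8..14. The standard-rate (11 Hz) trials are
# held to `equal_rate_fraction` of the condition's trials.
condition_rate_counts <- function(n_trials, delta, equal_rate_fraction,
                                  rates = 8:14, standard_rate = 11) {
  avail <- if (delta == 0) rates else seq(min(rates) + 1, max(rates) - 1)
  if (!standard_rate %in% avail) {
    stop("delta = ", delta, " incompatible with rate bounds ", min(rates),
         "..", max(rates))
  }
  n_equal <- round(equal_rate_fraction * n_trials)
  others <- setdiff(avail, standard_rate)
  n_rest <- n_trials - n_equal
  base <- n_rest %/% length(others)
  extra <- n_rest %% length(others)
  counts <- stats::setNames(rep(base, length(others)), others)
  if (extra > 0) {
    # deterministic allocation of the remainder: hardest rates first
    ord <- order(abs(others - standard_rate), decreasing = TRUE)
    counts[ord[seq_len(extra)]] <- counts[ord[seq_len(extra)]] + 1L
  }
  c(stats::setNames(n_equal, standard_rate), counts)
}

#' Default trial design
#'
#' Per-block trial counts for the nine task conditions: three unisensory
#' (AUD, VH, VL), two congruent audio-visual (AVH, AVL, delta = 0) and four
#' incongruent audio-visual cells (AVH/AVL crossed with delta = +2/-2).
#'
#' @param n_trials Trials per block (default 510).
#' @param equal_rate_fraction Fraction of each condition's trials presented
#'   at the 11 Hz standard rate (default 0.02).
#' @return A tibble with columns `modality`, `reliability`, `delta`,
#'   `n`, `equal_rate_fraction`.
#' @export
default_design <- function(n_trials = 510, equal_rate_fraction = 0.02) {
  cond <- tibble::tibble(
    modality    = c("AUD", "VIS", "VIS", "AV", "AV", "AV", "AV", "AV", "AV"),
    reliability = c("high", "high", "low", "high", "high", "high",
                    "low", "low", "low"),
    delta       = c(NA, NA, NA, 0, 2, -2, 0, 2, -2)
  )
  base <- n_trials %/% nrow(cond)
  extra <- n_trials %% nrow(cond)
  cond$n <- base + c(rep(1L, extra), rep(0L, nrow(cond) - extra))
  cond$equal_rate_fraction <- equal_rate_fraction
  cond
}

#' Generate a full trial table
#'
#' Expands a per-condition design into a pseudo-randomly ordered table of
#' trials, each carrying its event stream(s) as list-columns of onset times.
#' Audio-visual trials carry paired auditory and visual streams whose event
#' counts differ by exactly `delta`; the per-condition rate histogram matches
#' the design exactly (standard-rate trials at the configured fraction, the
#' remainder spread as evenly as possible over the other rates).
#'
#' @param design Tibble as returned by [default_design()].
#' @param subject_id Subject label stored on every row.
#' @param standard_rate Standard (comparison) stream rate in Hz.
#' @param include_streams Generate the per-trial event streams (default
#'   TRUE). Behaviour-only analyses that need only the rates can skip them.
#' @return A tibble with one row per trial: `trial_id`, `subject_id`,
#'   `modality`, `reliability`, `delta`, `rate` (experimental rate; the
#'   average rate on incongruent trials), `rate_aud`, `rate_vis`,
#'   `onsets_aud`, `onsets_vis` (list-columns), `is_equal_rate`.
#' @examples
#' tt <- generate_trial_table(default_design(90))
#' nrow(tt) # 90
#' @export
generate_trial_table <- function(design = default_design(),
                                 subject_id = "S01", standard_rate = 11,
                                 include_streams = TRUE) {
  needed <- c("modality", "reliability", "delta", "n", "equal_rate_fraction")
  if (!all(needed %in% names(design))) {
    stop("design must have columns ", paste(needed, collapse = ", "))
  }
  if (any(design$equal_rate_fraction < 0 | design$equal_rate_fraction > 1)) {
    stop("equal_rate_fraction must lie in [0, 1]")
  }
  rows <- purrr::pmap(design, function(modality, reliability, delta, n,
                                       equal_rate_fraction, ...) {
    d <- if (is.na(delta)) 0 else delta
    counts <- condition_rate_counts(n, d, equal_rate_fraction,
                                    standard_rate = standard_rate)
    rate <- rep(as.numeric(names(counts)), counts)
    tibble::tibble(modality = modality, reliability = reliability,
                   delta = delta, rate = rate)
  })
  tab <- dplyr::bind_rows(rows)
  tab <- tab[sample.int(nrow(tab)), , drop = FALSE]   # pseudo-random order
  tab$trial_id <- seq_len(nrow(tab))
  tab$subject_id <- subject_id
  tab$rate_aud <- ifelse(tab$modality == "VIS", NA,
                         ifelse(is.na(tab$delta), tab$rate, tab$rate - tab$delta / 2))
  tab$rate_vis <- ifelse(tab$modality == "AUD", NA,
                         ifelse(is.na(tab$delta), tab$rate, tab$rate + tab$delta / 2))
  tab$is_equal_rate <- tab$rate == standard_rate
  stream_or_null <- function(r) {
    if (is.na(r) || !include_streams) NULL else generate_event_stream(r)$onsets
  }
  tab$onsets_aud <- purrr::map(tab$rate_aud, stream_or_null)
  tab$onsets_vis <- purrr::map(tab$rate_vis, stream_or_null)
  dplyr::select(tab, "trial_id", "subject_id", "modality", "reliability",
                "delta", "rate", "rate_aud", "rate_vis", "is_equal_rate",
                "onsets_aud", "onsets_vis")
}

#' Write / read a trial table as CSV
#'
#' Onset lists are JSON-encoded so the table round-trips through plain CSV.
#'
#' @param trials Trial table from [generate_trial_table()] (possibly with a
#'   `choice` column added).
#' @param path Output file.
#' @return `write_trial_table()` returns `path` invisibly;
#'   `read_trial_table()` returns the tibble with list-columns restored.
#' @export
write_trial_table <- function(trials, path) {
  out <- trials
  for (col in c("onsets_aud", "onsets_vis")) {
    if (col %in% names(out)) {
      out[[col]] <- vapply(out[[col]], function(x) {
        if (is.null(x)) "" else as.character(jsonlite::toJSON(x, digits = NA))
      }, character(1))
    }
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  for (col in c("onsets_aud", "onsets_vis")) {
    if (col %in% names(out)) {
      out[[col]] <- purrr::map(out[[col]], function(x) {
        if (is.na(x) || !nzchar(x)) NULL else as.numeric(jsonlite::fromJSON(x))
      })
    }
  }
  out
}
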