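#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood fit of
#' \deqn{P(\mathrm{first\ higher} \mid rate) = \lambda + (1 - 2\lambda)\,
#'   \Phi\!\left(\frac{rate - \mu}{\sigma}\right)}
#' to binary "first stream higher" choices, with a fixed symmetric lapse
#' rate \eqn{\lambda}. The point of subjective equality (PSE) is \eqn{\mu};
#' the discrimination threshold is \eqn{\sigma}. Uncertainty comes from a
#' seeded nonparametric bootstrap over trials.
#'
#' @param rates Numeric vector of presented rates (Hz), one per trial. On
#'   incongruent audio-visual trials pass the average rate.
#' @param choices Binary vector (1 = "first stream higher"), same length.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param lapse Fixed lapse rate \eqn{\lambda} (default 0.01).
#' @param condition Optional condition label stored on the fit.
#' @return An object of class `psychometric_fit`: list with `mu`, `sigma`,
#'   `lapse`, `condition`, `n_per_rate` (tibble), `boot_mu`, `boot_sigma`,
#'   `separation` (logical flag for (near-)perfect separation), `logLik`.
#' @examples
#' set.seed(1)
#' r <- rep(8:14, each = 40)
#' ch <- rbinom(length(r), 1, pnorm(r, 11, 2))
#' fit <- fit_psychometric(r, ch, n_boot = 50)
#' round(c(fit$mu, fit$sigma), 2)
#' @export
fit_psychometric <- function(rates, choices, n_boot = 2000, lapse = 0.01,
                             condition = NULL) {
  stopifnot(length(rates) == length(choices))
  ok <- !is.na(rates) & !is.na(choices)
  rates <- rates[ok]; choices <- as.numeric(choices[ok])
  if (length(unique(rates)) < 2) {
    stop("need at least 2 distinct rates to fit a psychometric function")
  }
  if (length(unique(choices)) < 2) {
    stop("both choice outcomes must be present")
  }
  fit1 <- psy_mle(rates, choices, lapse)
  boot_mu <- boot_sigma <- rep(NA_real_, n_boot)
  n <- length(rates)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bf <- try(psy_mle(rates[idx], choices[idx], lapse), silent = TRUE)
    if (!inherits(bf, "try-error")) {
      boot_mu[b] <- bf$mu; boot_sigma[b] <- bf$sigma
    }
  }
  n_per_rate <- dplyr::count(tibble::tibble(rate = rates), .data$rate)
  structure(
    list(mu = fit1$mu, sigma = fit1$sigma, lapse = lapse,
         condition = condition, n_per_rate = n_per_rate,
         boot_mu = boot_mu, boot_sigma = boot_sigma,
         separation = fit1$separation, logLik = fit1$logLik),
    class = "psychometric_fit")
}

# ML core. Perfect separation drives sigma -> 0; the lower box bound keeps
# the optimum finite and the fit is flagged instead of aborting.
psy_mle <- function(rates, choices, lapse, sigma_min = 1e-3) {
  nll <- function(par) {
    p <- lapse + (1 - 2 * lapse) * stats::pnorm((rates - par[1]) / par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(choices * log(p) + (1 - choices) * log(1 - p))
  }
  start <- c(mu = stats::median(rates), sigma = max(stats::sd(rates), 0.5))
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(min(rates) - 10, sigma_min),
                      upper = c(max(rates) + 10, 100))
  list(mu = unname(opt$par[1]), sigma = unname(opt$par[2]),
       separation = opt$par[2] <= sigma_min * 1.01,
       logLik = -opt$value)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit>", if (!is.null(x$condition)) x$condition else "",
      sprintf(" mu = %.3f, sigma = %.3f (lapse %.3g, %d boot draws)\n",
              x$mu, x$sigma, x$lapse, length(x$boot_mu)))
  if (x$separation) cat("  note: near-perfect separation; sigma at bound\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_psychometric
#' @param x,conf_level A `psychometric_fit` and the bootstrap CI level.
#' @param ... Unused.
#' @export
tidy.psychometric_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  tibble::tibble(
    term = c("mu", "sigma"),
    estimate = c(x$mu, x$sigma),
    conf.low = c(stats::quantile(x$boot_mu, a, na.rm = TRUE),
                 stats::quantile(x$boot_sigma, a, na.rm = TRUE)),
    conf.high = c(stats::quantile(x$boot_mu, 1 - a, na.rm = TRUE),
                  stats::quantile(x$boot_sigma, 1 - a, na.rm = TRUE)))
}

#' @rdname fit_psychometric
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, sigma = x$sigma, lapse = x$lapse,
                 n = sum(x$n_per_rate$n), logLik = x$logLik,
                 separation = x$separation)
}

#' Predicted (Bayesian optimal) auditory weight
#'
#' Weight a statistically optimal observer assigns the auditory cue, from
#' the unisensory discrimination thresholds:
#' \deqn{W_{AUD} = \frac{1/\sigma_{AUD}^2}{1/\sigma_{AUD}^2 + 1/\sigma_{VIS}^2}.}
#' The visual weight is `1 - predicted_weight(...)`.
#'
#' @param sigma_aud,sigma_vis Unisensory thresholds (Hz), both > 0.
#' @return Predicted auditory weight in (0, 1).
#' @examples
#' predicted_weight(2, 2)       # 0.5
#' predicted_weight(2.19, 2.87) # auditory dominance
#' @export
predicted_weight <- function(sigma_aud, sigma_vis) {
  if (any(sigma_aud <= 0) || any(sigma_vis <= 0)) {
    stop("thresholds must be strictly positive")
  }
  (1 / sigma_aud^2) / (1 / sigma_aud^2 + 1 / sigma_vis^2)
}

#' Observed auditory weight from PSE shifts
#'
#' The apparent auditory weight on cue-conflict trials, from the shift of
#' the multisensory PSE between incongruent and congruent conditions:
#' \deqn{W_{AUD} = \frac{\mu_{AV}(\Delta) - \mu_{AV}(\Delta{=}0) + \Delta/2}{\Delta},}
#' where \eqn{\Delta} is the visual-minus-auditory rate difference.
#'
#' @param mu_delta PSE of the incongruent condition (Hz, average-rate axis).
#' @param mu_congruent PSE of the congruent (delta = 0) condition.
#' @param delta Rate conflict in Hz; must be nonzero.
#' @return Observed auditory weight (unbounded estimate; 0.5 means equal
#'   weighting).
#' @examples
#' observed_weight(12.25, 11.72, 2)
#' observed_weight(11.05, 11.72, -2)
#' @export
observed_weight <- function(mu_delta, mu_congruent, delta) {
  if (any(delta == 0)) stop("`delta` must be nonzero; the weight is undefined at delta = 0")
  (mu_delta - mu_congruent + delta / 2) / delta
}

#' Per-condition psychometric fits and perceptual weights for one subject
#'
#' Fits psychometric functions per condition (unisensory and audio-visual by
#' reliability and congruency) and derives predicted and observed weights.
#' Observed weights are averaged over the two congruency levels
#' (delta = +2, -2); all weights obey `w_vis = 1 - w_aud`.
#'
#' @param trials Trial table with a `choice` column (1 = "first higher").
#' @param n_boot Bootstrap draws per fit.
#' @param lapse Fixed lapse rate.
#' @return A list with `fits` (tibble: condition, mu, sigma, CI bounds) and
#'   `weights` (tibble: reliability, w_aud_pred, w_aud_obs_plus,
#'   w_aud_obs_minus, w_aud_obs, w_vis_obs).
#' @export
psychometric_weights <- function(trials, n_boot = 200, lapse = 0.01) {
  if (!"choice" %in% names(trials)) stop("trial table needs a `choice` column")
  cond_label <- function(m, r, d) {
    if (m == "AUD") "AUD"
    else if (m == "VIS") paste0("V", toupper(substr(r, 1, 1)))
    else sprintf("AV%s (d=%+d)", toupper(substr(r, 1, 1)), d)
  }
  cells <- dplyr::distinct(trials, .data$modality, .data$reliability, .data$delta)
  fits <- purrr::pmap(cells, function(modality, reliability, delta) {
    sub <- trials[trials$modality == modality &
                    trials$reliability == reliability &
                    (is.na(delta) | trials$delta %in% delta), ]
    f <- fit_psychometric(sub$rate, sub$choice, n_boot = n_boot, lapse = lapse,
                          condition = cond_label(modality, reliability,
                                                 if (is.na(delta)) 0L else as.integer(delta)))
    td <- tidy(f)
    tibble::tibble(condition = f$condition, modality = modality,
                   reliability = reliability, delta = delta,
                   mu = f$mu, sigma = f$sigma,
                   mu_lo = td$conf.low[1], mu_hi = td$conf.high[1],
                   sigma_lo = td$conf.low[2], sigma_hi = td$conf.high[2])
  })
  fits <- dplyr::bind_rows(fits)
  get1 <- function(m, r, d = NA) {
    row <- fits[fits$modality == m & fits$reliability == r &
                  (if (is.na(d)) is.na(fits$delta) | fits$delta == 0
                   else fits$delta %in% d), ]
    row[1, , drop = FALSE]
  }
  sigma_aud <- get1("AUD", "high")$sigma
  weights <- purrr::map_dfr(c("high", "low"), function(rel) {
    sigma_vis <- get1("VIS", rel)$sigma
    mu0 <- fits$mu[fits$modality == "AV" & fits$reliability == rel &
                     fits$delta == 0]
    mup <- fits$mu[fits$modality == "AV" & fits$reliability == rel &
                     fits$delta == 2]
    mum <- fits$mu[fits$modality == "AV" & fits$reliability == rel &
                     fits$delta == -2]
    wp <- if (length(mup)) observed_weight(mup, mu0, 2) else NA_real_
    wm <- if (length(mum)) observed_weight(mum, mu0, -2) else NA_real_
    w_obs <- mean(c(wp, wm), na.rm = TRUE)
    tibble::tibble(reliability = rel,
                   w_aud_pred = predicted_weight(sigma_aud, sigma_vis),
                   w_aud_obs_plus = wp, w_aud_obs_minus = wm,
                   w_aud_obs = w_obs, w_vis_obs = 1 - w_obs)
  })
  list(fits = fits, weights = weights)
}

#' Select visual-reliability SNR levels from a calibration curve
#'
#' Fits a logistic performance-vs-SNR curve to visual calibration data and
#' returns, by inverse interpolation, the SNR at which visual performance
#' matches auditory performance (high reliability) and the SNR at which it
#' is `drop` percentage points lower (low reliability).
#'
#' @param snr_grid Calibration SNR levels.
#' @param performance_per_snr Proportion correct at each SNR, in (0, 1).
#' @param auditory_performance Proportion correct on the auditory
#'   calibration block.
#' @param drop Performance drop (proportion, default 0.30) defining the
#'   low-reliability level.
#' @return Named numeric vector `c(snr_high =, snr_low =)`.
#' @export
select_reliability_levels <- function(snr_grid, performance_per_snr,
                                      auditory_performance, drop = 0.30) {
  stopifnot(length(snr_grid) == length(performance_per_snr))
  if (any(performance_per_snr <= 0 | performance_per_snr >= 1)) {
    stop("performance values must lie strictly in (0, 1)")
  }
  fit <- stats::lm(stats::qlogis(performance_per_snr) ~ snr_grid)
  a <- stats::coef(fit)[1]; b <- stats::coef(fit)[2]
  if (b <= 0) stop("performance curve is not increasing in SNR")
  invert <- function(target, what) {
    lo <- stats::plogis(a + b * min(snr_grid))
    hi <- stats::plogis(a + b * max(snr_grid))
    if (target < lo || target > hi) {
      stop(what, " target ", signif(target, 4),
           " outside achievable performance range [",
           signif(lo, 4), ", ", signif(hi, 4), "]")
    }
    unname((stats::qlogis(target) - a) / b)
  }
  c(snr_high = invert(auditory_performance, "high-reliability"),
    snr_low = invert(auditory_performance - drop, "low-reliability"))
}
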