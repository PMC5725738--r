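---
title: "Methods: reliability-weighted audio-visual integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reliability-weighted audio-visual integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avweights)
```

# The scientific problem

When an observer judges a property of the world that is signalled by two
senses at once — here, the rate of a stream of brief audio-visual events —
the percept behaves like a weighted average of the unisensory estimates.
Bayesian cue-combination theory predicts the weights from the reliabilities
(inverse variances) of the individual cues:

$$W_{AUD} = \frac{1/\sigma_{AUD}^2}{1/\sigma_{AUD}^2 + 1/\sigma_{VIS}^2},
\qquad W_{VIS} = 1 - W_{AUD}.$$

This package implements a complete analysis chain for testing *when* during
a trial neural signals reflect (a) the physical reliability of the cues and
(b) the perceptual weights the observer actually applies — plus a synthetic
generator with known ground truth against which every stage can be
validated.

# Task and stimuli

* Each trial presents streams of 12 ms events (auditory clicks and/or
  visual flashes) inside a 900 ms window. Inter-event gaps are drawn from
  {48, 96} ms and a leading pause of one gap is inserted with probability
  0.5, so event timing varies across trials with a fixed event count.
  `generate_event_stream()` uses rejection sampling (capped at 10,000
  attempts) over gap compositions that exactly fill the window.
* Rates span 8–14 Hz; the observer reports whether the stream rate exceeds
  the 11 Hz standard.
* Conditions: auditory only (AUD), visual with high/low reliability
  (VH/VL), and audio-visual with high/low visual reliability (AVH/AVL).
  Audio-visual trials carry a rate conflict $\Delta \in \{0, \pm 2\}$ Hz
  (visual minus auditory), applied symmetrically around the nominal
  average rate. 2% of each condition are equal-rate (11 Hz) catch trials.
* The running stimulus evidence is the *accumulated rate*: the number of
  events with onset before each successive 12 ms bin edge
  (`accumulated_rate()`, 75 samples for a 900 ms stream).

# Behavioural analyses

**Psychometric curves** (`fit_psychometric()`): the proportion of "rate
higher than standard" reports as a function of (average) rate is fitted
with a cumulative Gaussian with a fixed lapse rate,
$P = \lambda + (1-2\lambda)\Phi((r-\mu)/\sigma)$, by maximum likelihood
(L-BFGS-B; $\sigma \ge 10^{-3}$, fits pinned at that bound are flagged as
separation). Confidence intervals come from a nonparametric bootstrap over
trials. $\lambda = 0.01$ absorbs stimulus-independent errors without
letting extreme rates dominate the fit.

**Observed weights** (`observed_weight()`): with a conflict $\Delta$, the
point of subjective equality (PSE) on the average-rate axis shifts in
proportion to the weight given to the cue that moved:

$$W_{AUD} = \frac{\mu_{AV}(\Delta) - \mu_{AV}(0) + \Delta/2}{\Delta}.$$

A useful identity of the generative observer model: if choices follow
$w\,\hat r_A + (1-w)\,\hat r_V$ with unbiased unisensory estimates, the PSE
equals $11 - \Delta/2 + w\Delta$, so the estimator recovers $w$ exactly and
averaging the $\pm\Delta$ estimates cancels errors in $\mu_{AV}(0)$.

**Time-resolved perceptual weights** (`time_resolved_weights()`): at each
time $t$ (24–600 ms, 12 ms steps), choice is modelled by logistic
regression on the z-scored accumulated auditory and visual rates of
incongruent AV trials. The iteratively reweighted least squares solver adds
a ridge of $10^{-6}$ (excluding the intercept) purely for numerical
stability; perfectly collinear or constant designs (e.g. before the first
event) are flagged, not fitted. Weights are normalised
$w = \beta/(\beta_{AUD}+\beta_{VIS})$ when both coefficients are positive;
otherwise raw coefficients are kept and flagged. Predictive performance is
the area under the ROC (Az) of 10-fold stratified cross-validated scores;
Az is computed by the rank-sum identity $Az = U/(n_1 n_0)$.

# EEG decoding and neural weights

`simulate_eeg()` generates epochs (trials × channels × time) from a
forward model: each event evokes a gamma-shaped kernel (peak 100 ms, width
50 ms, peak-normalised) at a modality-specific latency (visual 90 ms,
auditory 160 ms), scaled by reliability-dependent gains and projected to
the sensors through smooth unit-norm mixing vectors; sensor noise is
spatially correlated (exponential decay over the channel axis).

**Decoding** (`train_decoder()`, `decoder_az()`): a regularised linear
discriminant ($w = \hat\Sigma^{-1}(m_1-m_0)$ with
$\hat\Sigma = (1-\gamma)S + \gamma\,\nu I$, $\nu$ = mean diagonal of $S$,
$\gamma$ from an analytic Ledoit–Wolf-style shrinkage estimate) is trained
at each 55 ms window (onset-aligned, 5 ms grid, 25–600 ms) to separate
rates above vs. below the standard, using congruent AV trials only
(equal-rate trials excluded). The discriminant output $Y$ is then applied
to all trials. Significance of the cross-validated Az curve uses a
max-statistic permutation threshold ($\alpha = 0.01$). Scalp patterns use
the forward-model correlation between $Y$ and the windowed channel data.

**Neural weights** (`neural_weight_regression()`): $Y(t)$ is regressed on
the z-scored accumulated auditory and visual rates of incongruent AV
trials (OLS; ridge fallback only if the condition number exceeds $10^6$),
separately per reliability, over 24–400 ms. These weights are deliberately
*not* normalised: the neural sources of the auditory and visual
contributions need not share a scale. The classifier's informative window
is itself an empirical question; the analysis window is configurable
(`window_neural`) because "0–400 ms" and "24–400 ms" conventions differ
only in whether pre-first-bin points (which are degenerate anyway) are
included.

# Statistics

* **Cluster-based permutation** (`cluster_permutation()`): paired t values
  per time point; runs of at least 2 points with $|t| > 1.8$ form
  clusters; the cluster statistic is its size, and the null is the maximal
  cluster size under random subject sign-flips (positive and negative runs
  both enter the null maximum, giving two-sided control).
  $p = (1 + \#\{null \ge obs\})/(1 + n_{perm})$ so p is never exactly 0.
  The size statistic (rather than mass) makes the exhaustive small-sample
  oracle exact and matches the reporting convention of cluster extents.
* **Correlation clusters** (`cluster_permutation_cor()`): Spearman rho per
  time point, t-transformed, with subject assignment permuted.
* **Max-statistic thresholds** (`max_stat_threshold()`): the
  $(1-\alpha)$ quantile of the permutation distribution of the series
  maximum; a warning is emitted when $n_{perm}\alpha < 5$ (unstable tail).
* **Effect sizes**: two-sided Wilcoxon signed-rank Z (normal approximation
  with tie correction; exact enumeration via the signed-rank distribution
  when untied and $n \le 50$) and $r = Z/\sqrt{N}$.
* **Neuro-behavioural coupling** (`neuro_behavioral_correlation()`): the
  reliability influence $D(t) = [W_{AUD}-W_{VIS}]_{high} -
  [W_{AUD}-W_{VIS}]_{low}$ is computed for perceptual and neural weights,
  correlated across subjects at each time point (perceptual series aligned
  to the neural grid by nearest neighbour), and cluster-corrected.

# The synthetic observer and group

`observer_params()` defaults ($\sigma_{AUD} = 2.19$,
$\sigma_{VIS,high} = 2.87$, $\sigma_{VIS,low} = 4.55$, auditory weights
0.80/0.84 for high/low visual reliability, lapse 0.01) represent a group
that *over-weights* audition relative to the Bayesian prediction — the
empirically typical pattern for temporal judgements. `sample_subjects()`
adds subject effects on the log-odds of the low-reliability auditory
weight (SD 1.5, so roughly half the group shifts opposite to the
reliability prediction, as real groups do) and, when `coupled = TRUE`,
re-uses the same standardized effect to scale the low-reliability neural
gains (gain scale SD 0.45, floored at 0.2). This makes behavioural and
neural reliability effects share a subject-level cause with an attainable
between-subject correlation of about 0.5 — detectable, but far from
deterministic — while `coupled = FALSE` provides a matched null.

What the generator does *not* emulate: oscillatory EEG background,
artefacts, volume-conduction head geometry, decision/motor signals late in
the trial, or trial-to-trial attention fluctuations. It is a validation
instrument for the analysis chain, not a biophysical simulation.

# Numerical choices

| Choice | Value | Rationale |
|---|---|---|
| logistic ridge | 1e-6 | numerical stability only; excluded from intercept |
| lapse rate | 0.01 (fixed) | keeps the MLE well-posed at extreme rates |
| sigma lower bound | 1e-3 | flags separation instead of diverging |
| LDA shrinkage | analytic (Ledoit–Wolf-style) | works at 40–500 trials per class |
| rejection cap | 10,000 | infeasible rate/duration pairs error out |
| neural ridge fallback | condition number > 1e6 | OLS elsewhere |
| cluster threshold | t = 1.8, min size 2 | study convention; calibration verified by simulation |
| permutation p | (1 + hits)/(1 + n) | never exactly zero |

# Worked example

```{r example, eval = FALSE}
cfg <- study_config(n_subjects = 6, trials_per_subject = 180,
                    fwd = eeg_forward_params(n_channels = 16),
                    fs = 100, n_perm_cluster = 200, n_boot = 50)
res <- run_pipeline(cfg, keep_eeg = TRUE, verbose = TRUE)
res$weights                      # per-subject psychometric weights
res$stats$percept_aud_rel        # reliability effect on perceptual weights
res$stats$neuro_behav$clusters   # neuro-behavioural correlation clusters
plot_weight_series(res$pweights)
```

# Open questions and decisions

* The discriminant is trained on congruent AV trials only and applied
  everywhere; training on all trials would mix the conflict manipulation
  into the decoding axis.
* Cluster statistic = size (not mass). Mass weights strong short effects
  more; size matches the extent-based reporting the analyses target and
  admits an exact enumeration oracle.
* Epoch containers are RDS files with a fixed logical layout
  (data, times, channels, trial_id); trial tables are CSV with
  JSON-encoded onset lists, so studies round-trip as plain files.
* Problem sizes used in examples and tests (6–20 subjects, 16–64 channels,
  100–200 Hz) are this package's own scaling choices; all analysis
  parameters are exposed through `study_config()`.
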