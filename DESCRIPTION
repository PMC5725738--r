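Package: avweights
Title: Reliability-Weighted Audio-Visual Integration: Behaviour, EEG Decoding and Permutation Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying reliability-based cue weighting in audio-visual
    rate discrimination. Generates event-stream stimuli and synthetic
    behavioural and EEG data with known ground truth, fits cumulative-Gaussian
    psychometric functions and derives predicted (Bayesian optimal) and
    observed perceptual weights, estimates time-resolved perceptual weights by
    logistic regression on accumulated sensory evidence, decodes stimulus rate
    from multichannel EEG with sliding-window regularized linear discriminant
    analysis, derives neural sensory weights by regression of the discriminant
    output on accumulated rates, and links behavioural and neural reliability
    effects with cluster-based permutation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
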