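Package: gaeeg
Title: Spectral EEG Analysis of the Phases of General Anesthesia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of frontal EEG recorded under
    general anesthesia: artifact flagging and wavelet quantile normalization,
    weighted-average spectrograms and band-power series, segmentation of
    iso-electric and alpha-band suppressions by a dual-envelope threshold rule,
    sigmoid fitting of the recovery-of-consciousness band-power decays with
    emergence-trajectory markers (duration and frequency shifts), total-variation
    instability statistics of the smoothed peak-frequency tracks, and a Bayesian
    correlation battery (Pearson and partial correlations with Zellner-Siow
    g-prior Bayes factors and Jeffreys evidence labels). A calibrated synthetic
    cohort generator with full ground-truth annotations makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
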