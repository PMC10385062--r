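Package: frugalhr
Title: Frugal Motion-Aware Correction of Wrist Heart-Rate Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects the noisy heart-rate readings of low-cost wrist
    wearables (photoplethysmography sensors) against a chest-worn ECG
    reference using a tiny dense neural network that takes a sliding window
    of past heart-rate readings together with median, maximum and
    interquartile-range summaries of the wrist acceleration recorded between
    readings. Provides the full pipeline: reading and nearest-timestamp
    alignment of the device, reference and acceleration streams; feature
    construction with train-set normalization; training of the compact
    regressor with Adam, L2 kernel regularization and early stopping;
    architecture grid search with repeat aggregation and size-aware
    final-model selection; evaluation against raw and moving-average
    baselines; a frugality score trading error against memory-times-compute
    cost; a constant-memory streaming emulation of the on-device
    implementation; and a synthetic session generator with activity-driven
    heart-rate dynamics and motion-dependent measurement noise so that every
    stage is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    arrow,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
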