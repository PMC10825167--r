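Package: pftm
Title: Pupil Frequency-Tagging for Chromatic Equiluminance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimate an observer's chromatic equiluminance point from
    reflexive pupil oscillations. A disc alternating between a fixed and a
    variable luminance at a slow tagging frequency (~1.77 Hz) drives a pupil
    oscillation whose amplitude at that frequency is minimal when the two
    colours are perceptually equiluminant, with a ~180 degree phase reversal
    across the minimum. The package provides stimulus-locked preprocessing
    (Gaussian smoothing, baseline correction, trial averaging, downsampling),
    single-bin FFT amplitude and phase extraction over integer-cycle windows,
    smoothing-spline localisation of the amplitude minimum confirmed by the
    phase transition, companion psychophysical estimators (minimum-flicker
    matching and minimum-motion 2AFC with a Quick-function maximum-likelihood
    fit), method-agreement statistics (Pearson/Spearman with Fisher z,
    Bland-Altman limits of agreement), and a synthetic pupil-session
    simulator that provides ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
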