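Package: patrec
Title: Pulse Arrival Time Recovery Trends from Synchronized ECG and PPG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cuff-less blood-pressure trend analysis based on beat-by-beat
    Pulse Arrival Time (PAT) extracted from synchronized ECG and photoplethysmography
    (PPG) recordings. Implements the full processing chain: zero-phase notch and
    Butterworth band-pass filtering, Pan-Tompkins QRS detection, PPG maximum-slope
    fiducial localization, per-cycle median PAT with rolling-window quality control,
    mono-exponential post-exercise recovery modelling, Recovery Index normalization
    against intermittent cuff systolic pressure, and an agreement-statistics battery
    (Shapiro-Wilk / Kruskal-Wallis / Mann-Whitney with Bonferroni correction,
    subject-wise Pearson correlation with z-score screening, Bland-Altman limits of
    agreement, and Lin's concordance correlation coefficient). A synthetic campaign
    generator reproduces the acquisition protocol (2 sessions x 11 cycles of 10 s
    synchronized 1 kHz signals with intermittent cuff readings) with exact
    ground-truth fiducials for validation.
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
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
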