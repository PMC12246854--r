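Package: stressphys
Title: Multimodal Stress-Recovery Analysis for fNIRS, EDA and Salivary Cortisol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for analysing multimodal physiological
    recordings from staged stress-and-recovery experiments. Provides readers
    for wrist-device electrodermal activity (EDA) CSV exports, European Data
    Format (EDF) functional near-infrared spectroscopy (fNIRS) recordings and
    salivary cortisol panels; EDA artifact detection and repair, Butterworth
    smoothing, min-max normalisation and tonic-level stage summaries;
    modified Beer-Lambert conversion of optical densities to haemoglobin
    concentration changes with age-adjusted differential pathlength factors,
    scalp-coupling-index channel quality control, zero-phase band-pass
    filtering and rolling-window stage averages; a prefrontal Laterality
    Index Response statistic; cortisol trajectory metrics; and the
    stage-by-group statistical battery (Levene, paired and independent
    t-tests with Cohen's d, mixed repeated-measures ANOVA with eta-squared).
    A synthetic-cohort generator with known ground truth makes every pipeline
    stage testable without access to raw participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    signal,
    zoo,
    car,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
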