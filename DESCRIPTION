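Package: amnoise
Title: Noise-Probing Psychophysics of Amplitude-Modulation Cues in Music and
    Speech Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes noise stimuli whose amplitude-modulation (AM) spectrum
    follows a 1/f-weighted shifted lognormal with a designated peak frequency
    and temporal-regularity width, modulated onto a low-noise-noise carrier;
    builds headphone-screening stimuli and the trial schedules of four
    music/speech judgment experiments; simulates participant populations with
    heterogeneous response slopes, lapses, musical-sophistication covariates
    and non-compliant archetypes; and runs the full behavioral analysis
    pipeline (exclusion filters, per-participant linear and bounded-logistic
    psychometric fits, one-sample slope inference with Cohen's d, covariate
    correlations with outlier handling, unequal-variance split-group tests,
    and exact noncentral-t power analysis), so every stage of the study design
    is reproducible and testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
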