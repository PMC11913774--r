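Package: dyadsync
Title: Interpersonal Cardiac Synchrony Analysis for Dyadic Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying interpersonal physiological synchrony from
    two-person electrocardiogram recordings. Implements the full analysis path
    from raw ECG to inter-beat-interval (IBI) series (band-pass filtering,
    R-peak detection, artifact interpolation, 4 Hz resampling), ARIMA
    prewhitening with exhaustive order search and Guerrero Box-Cox lambda
    selection, lagged cross-correlation synchrony with lag-group summaries and
    Fisher Z transformation, a participant-shuffling pseudo-dyad surrogate
    null with Welch comparisons, rMSSD heart-rate-variability change scores,
    behavioral synchrony measures with Tukey outlier filtering, and dyad-level
    mixed-model designs with sum and absolute-difference within-dyad
    predictors. A synthetic-study generator with a controllable shared
    autonomic driver provides ground-truth data for validation and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
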