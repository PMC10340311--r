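Package: sdbreath
Title: Sleep-Disordered Breathing Detection from ECG and Respiratory Effort
Version: 0.1.0
Authors@R:
    person("SDB", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for detecting
    sleep-disordered breathing (SDB) events from cardiorespiratory signals.
    Includes an annotated synthetic night generator (beat times with cyclic
    heart-rate variation, respiration-modulated ECG, effort-belt amplitude
    reductions during apneas and hypopneas, hypnogram and body-position
    tracks), signal preprocessing into 4 Hz RR, ECG-derived respiration (EDR)
    and respiratory-effort series, a bidirectional-GRU sequence labeler
    emitting 1 Hz event probabilities, event-based scoring under a strict
    first-overlap matching rule and an any-overlap rule, apnea-hypopnea index
    (AHI) estimation, and subject-level agreement statistics (Bland-Altman,
    Spearman, two-way random-effects ICC, severity confusion/accuracy/kappa
    with near-boundary double-labeling).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
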