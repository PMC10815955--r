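Package: gammassr
Title: Gamma-Band ASSR Phase Locking, Spontaneous Gamma Power and
    Behavioral Endpoints for Rodent EEG Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for preclinical EEG biomarker studies in
    NMDA-receptor-antagonist rodent models: auditory steady-state response
    (ASSR) phase-locking factor estimation from Morlet wavelet time-frequency
    decompositions, quantitative EEG gamma band power from Hanning
    periodograms, locomotor-activity and social-interaction endpoint
    aggregation, and a group-statistics layer (two-standard-deviation outlier
    removal, one-way ANOVA, Dunnett many-to-one comparisons, percent-of-reference
    reporting). Includes a seeded synthetic-data generator with closed-form
    expected values (von Mises trial-phase jitter, 1/f plus band-limited gamma
    background, injected artifacts, negative-binomial activity counts) so every
    stage is testable without animal recordings, plus EDF and columnar-text I/O.
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
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    mvtnorm,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
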