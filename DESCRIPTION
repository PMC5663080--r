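Package: raiqc
Title: Data Quality Evaluation for interRAI Home and Community Care
    Assessment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the quality of longitudinal interRAI
    assessment data (RAI-HC and interRAI CHA) as collected in home and
    community care. Provides eligibility filtering and annual record
    selection, scoring of the interRAI summary scales (ADL Hierarchy, ADL
    Long Form, IADL performance and capacity, Depression Rating Scale,
    Cognitive Performance Scale, CHESS, Pain Scale, MAPLe), year-over-year
    trend tables, convergent-validity correlations, Cronbach's alpha
    reliability trends, detection of possible auto-population
    (carry-forward) in within-year reassessment pairs, and cross-cohort
    comparison of indicator batteries. A synthetic cohort generator with a
    latent-factor ordinal item model makes the full pipeline testable
    without access to confidential assessment records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
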