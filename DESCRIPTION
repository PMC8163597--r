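Package: consistr
Title: Consistency Analytics for Longitudinal Workplace-Based Clinical
    Assessment Records
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse per-observation workplace-based assessment
    records scored on an ordinal developmental-indicator (DI) scale of
    learner independence. Implements the per-student "consistency"
    statistic (the fraction of procedures whose weakest stage meets an
    independence threshold), a binary case-difficulty rule for dental
    restorations, experience-group stratification with descriptive
    tables, cohort-equivalence testing, year-of-study comparisons with
    Bonferroni-adjusted post-hoc contrasts, and the volume-versus-
    consistency correlation. A seeded synthetic-cohort generator emulates
    multi-year clinical observation data so the full pipeline can be
    exercised and calibrated without access to identifiable student
    records.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
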