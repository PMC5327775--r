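Package: cmlrisk
Title: Prognostic Risk Scores and Consistency Analysis for Chronic
    Myeloid Leukemia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Computes the four baseline prognostic scores used in chronic
    myeloid leukemia (Sokal, Hasford, EUTOS and ELTS) from diagnosis-time
    clinical and hematological variables, maps each score to its published
    risk category, and analyses agreement between the scores against major
    molecular response (MMR): dichotomized risk grouping under two
    intermediate-merging strategies, 2x2 contingency-table accuracy,
    enumeration of joint risk-label combinations, and a consensus/conflict
    partition with per-score subgroup accuracies. Also provides a synthetic
    cohort generator matching published baseline distributions and a
    reconstruction routine that builds patient-level cohorts whose
    aggregate tables match published combination counts, so the whole
    analysis is reproducible end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
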