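Package: pufanon
Title: Anonymization and Statistical-Bias Evaluation for Clinical Public Use Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preparing and auditing anonymized public use files
    (PUFs) from clinical cohort data. Implements expert risk triage of
    variables (replicability/availability/distinguishability scoring),
    record suppression enforcing k-anonymity on key variables and
    t-closeness on sensitive variables with a monotone incremental-release
    mode, prosecutor-model re-identification risk profiles, and a
    statistical-bias evaluation harness (frequency comparisons, chi-squared
    tests, case-fatality-rate and fraction-published curves over growing
    datasets, adjusted logistic odds-ratio comparisons). Ships a seeded
    synthetic generator for a three-cohort COVID-19 registry so the whole
    pipeline can be exercised without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
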