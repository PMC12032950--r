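Package: faersdpa
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on FDA Adverse
    Event Reporting System (FAERS) style quarterly report files: parsing of
    the $-delimited DEMO/DRUG/REAC/OUTC/THER tables, case deduplication,
    drug-name normalisation, preferred-term to system-organ-class rollup,
    2x2 contingency construction, and four disproportionality statistics
    (reporting odds ratio, proportional reporting ratio with chi-square,
    Bayesian confidence propagation information component, and empirical
    Bayes geometric mean) with interval bounds and screening thresholds.
    Includes a synthetic report generator with planted signals for
    validation, reconstruction of 2x2 tables from published signal tables,
    and descriptive summaries of report demographics and time to onset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
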