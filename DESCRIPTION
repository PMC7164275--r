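Package: rhinorep
Title: Repeatability and Reproducibility Analysis for Anterior Active
    Rhinomanometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing test-retest repeatability and
    between-visit reproducibility of clinical measurements, motivated by
    anterior active rhinomanometry (AAR) in children. Implements the
    one-way random-effects intraclass correlation coefficient with an
    F-test against a non-zero null value, per-subject and pooled
    coefficients of variation, nonparametric Bland-Altman agreement
    limits, Zou's sample-size method for ICC hypothesis tests, a
    Bland-Altman agreement sample-size helper, DeLong confidence
    intervals and cross-validated AUC for ROC analysis, Monte-Carlo
    simulation engines contrasting ICC- and CV-based repeatability
    indices, and a synthetic study generator emulating a five-group
    paediatric rhinomanometry design with an end-to-end analysis
    pipeline and command-line interface.
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
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
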