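Package: clinpipe
Title: Privacy-Conscious Clinical Data Pipelines with Multilabel
    Prediction and Privacy Auditing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for building and auditing
    privacy-conscious clinical data pipelines on electronic health record
    (EHR) encounter tables. Provides a synthetic EHR generator with
    correlated disease labels and configurable data-quality defects;
    deidentification via surrogate identifiers, ISO-8601 date
    standardization and k-anonymity generalization with verification;
    episode segmentation, 90-day rolling-window features, monthly
    aggregates and target-condition extraction; dual-format (CSV/Parquet)
    persistence with round-trip guarantees and a paired-run timing
    harness; signed feature hashing into 2^18-dimensional sparse vectors
    with leakage exclusion and patient-level splits; one-vs-rest and
    classifier-chain ensembles of gradient-boosted trees; discrimination,
    multilabel and calibration metrics with paired testing, TOST
    equivalence and bootstrap confidence intervals; and a
    membership-inference attack suite (confidence, entropy, loss, shadow,
    LiRA) for model privacy audits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    Matrix,
    xgboost,
    arrow,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
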