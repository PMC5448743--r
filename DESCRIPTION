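Package: seromir
Title: Serum miRNA Marker Discovery and Incremental Cardiovascular Risk Value
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for two-panel serum microRNA profiling studies: hemolysis
    quality control, cycle-threshold (Ct) cleaning and delta-Ct relative
    quantification, model-based (NormFinder-type) reference-miRNA stability
    selection over single miRNAs and pairs, fold-change plus t-test candidate
    filtering followed by forward stepwise discriminant analysis, forward
    logistic risk modelling with leave-one-out cross-validation, and
    incremental-value assessment of a marker added to established
    cardiovascular risk markers (sensitivity/specificity/accuracy, ROC AUC
    with a paired DeLong comparison, continuous net reclassification
    improvement and integrated discrimination improvement). Includes a
    synthetic-cohort generator with planted stable and differential miRNAs
    and clinical covariates for end-to-end testing with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    readxl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
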