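Package: rpsubtype
Title: Ensemble Sparse Random Projection Classification of Molecular
    Subtypes from Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies molecular subtypes of B-cell acute lymphoblastic
    leukemia (B-ALL) from bulk gene expression using ensembles of very
    sparse random projections and linear support vector machines with
    calibrated class probabilities. Includes expression preprocessing
    (gene prevalence filtering, TPM conversion, log transformation,
    subtype-label harmonization), Johnson-Lindenstrauss style distance
    preservation diagnostics, imbalance-aware evaluation (per-class and
    multiclass accuracy, F1 and Matthews correlation coefficient,
    repeated stratified cross-validation, stratified hold-out),
    prediction-informed two-dimensional visualization, and a synthetic
    expression-cohort simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    e1071,
    MASS,
    cluster,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
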