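Package: pathscreen
Title: Multiplexed Reporter Drug-Screen Analysis with Visual Barcode Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for pooled live-cell reporter drug screens in
    which clonal identity is encoded by fluorescent proteins targeted to
    distinct subcellular compartments ("visual barcodes"). Provides a
    synthetic-data generator for barcode image sets, per-cell reporter
    tables with a planted two-state response structure, growth time courses
    and cohort proteome matrices; nucleus/cell segmentation, cytological
    profiling and supervised barcode calling with confusion diagnostics;
    signed two-sample Kolmogorov-Smirnov activity scoring with a
    control-derived significance threshold; PCA-based signaling-state
    metrics (variance-product persistence, conformity, adherence, drug
    strength) and Ward clustering of drug signatures; interaction-penalized
    ridge deconvolution of drug-target effects with cross-validated
    penalties; exponential growth/division fitting with control
    normalization and imbalance scoring; and correlation-matrix similarity
    of cohort proteomes against a reference panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    xgboost,
    MASS,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    mclust,
    withr
Config/testthat/edition: 3
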