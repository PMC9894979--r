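Package: gastroscape
Title: Malignancy Calling, Differentiation Signatures and Tumor Ecosystem
    Analysis for Gastric Cancer Single-Cell RNA-Seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for single-cell RNA-seq studies of gastric
    cancer heterogeneity. Implements expression-inferred copy-number profiling
    with a windowed mean-squared-deviation malignancy score, a three-step
    malignant/non-malignant classification combining clustering with CNV
    evidence, derivation of a tumor-differentiation gene signature by a
    correlation/lasso/random-forest cascade, per-cell gene-set scoring
    (binned-control module scores, ssGSEA-style enrichment, AUC recovery
    scores), per-sample non-negative matrix factorization with cross-sample
    meta-program extraction, a PCA-based trans-differentiation pseudotime from
    differentiated adenocarcinoma to neuroendocrine carcinoma, NATMI-style
    ligand-receptor edge extraction, and median-split survival analysis.
    Ships a synthetic cohort generator with ground truth so every stage is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    irlba,
    scran,
    glmnet,
    randomForest,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cnv.R'
    'communication.R'
    'io.R'
    'metaprograms.R'
    'pipeline.R'
    'preprocess.R'
    'scoring.R'
    'signature.R'
    'simulate.R'
    'survival.R'
    'trajectory.R'
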