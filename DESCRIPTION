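Package: cfpe
Title: Preeclampsia Risk Prediction from Low-Coverage cfDNA Promoter Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline that predicts early- and late-onset
    preeclampsia from low-coverage (NIPT-style) maternal plasma cell-free
    DNA sequencing. Quantifies read coverage in 2 kb promoter windows
    centered on transcription start sites, normalizes it as RPKM and as
    multiples of the per-dataset control median (MoM), screens samples by
    PCA, selects stably differential promoters by subsampled Wilcoxon
    stability selection, assembles clinical and cfDNA feature vectors, and
    trains and evaluates logistic-regression and random-forest classifiers
    with bootstrap AUC confidence intervals, fixed-specificity operating
    points and DeLong AUC comparisons. Includes a seeded multi-hospital
    synthetic cohort generator so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    graphics,
    grDevices,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
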