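Package: loadscreen
Title: Genetic Load Scoring and Drug-Sensitivity Association Screens for
    Cancer Cell Line Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the cumulative burden of passenger alterations
    ("genetic load") in cancer cell lines from segmented copy-number
    profiles (mean absolute alteration volume) and point-variant tables
    (driver-excluded, allelic-fraction-filtered variant counts), and tests
    whether load predicts drug sensitivity measured as dose-response
    activity area. Provides tissue-wise z-normalisation; pan-cancer,
    pan-drug and tissue-drug rank-correlation screens with one-sided tests
    under Benjamini-Hochberg FDR control; a lasso-combined two-load
    predictor; a rank-based single-sample gene-set enrichment layer linking
    load to expression programs; and a fully seeded synthetic-cohort
    generator with known planted effects for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: Software, CopyNumberVariation, Pharmacogenomics,
    GeneExpression, StatisticalMethod
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
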