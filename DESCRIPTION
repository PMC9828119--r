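Package: timephen
Title: Tumor Immune Microenvironment Phenotyping and Outcome Modelling for
    Multiplex Immunofluorescence Tissue Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the tumor immune microenvironment (TIME) of
    tissue-microarray cohorts profiled by multiplex immunofluorescence. Starting
    from per-cell tables (coordinates, tumor/stroma compartment, marker
    positivity for CK, CD8, CD68, FOXP3, PD-1 and PD-L1), the package computes
    per-core immune population densities, marker fractions and tumor-stroma
    gradients; discovers immune phenotypes by hierarchical clustering with
    bootstrap Jaccard stability and rule-based semantic naming; quantifies
    radius-based cell-cell spatial interactions; aggregates cores to patients
    and builds relapse-prediction models by exhaustive feature-subset logistic
    regression with repeated cross-validation, ROC/Youden stratification,
    bootstrap model comparison and Kaplan-Meier curves; and fits CART surrogate
    trees mapping intra-tumoral single-marker densities to phenotypes. A seeded
    synthetic TMA-cohort generator with known ground truth makes the whole
    pipeline runnable and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    mclust,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
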