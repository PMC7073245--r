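Package: histoprog
Title: Histopathology Image Features for Survival Prognosis and Subgroup
    Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for prognostic analysis of
    hematoxylin-and-eosin (H&E) histopathology images. Implements optical
    density transformation, Macenko-style stain-matrix estimation, stain
    normalization to a reference, and density-space color augmentation;
    random patch sampling with tissue filtering; pluggable per-crop feature
    extraction with hierarchical median aggregation to per-image and
    per-subject feature vectors; PCA + t-SNE visualization and
    cross-validated linear-SVM tumor/normal classification; univariate and
    elastic-net-penalized Cox proportional hazards survival modelling with
    concordance evaluation and Kaplan-Meier/log-rank comparison; K-means
    subgroup discovery with silhouette and Davies-Bouldin model selection;
    and FDR-controlled correlation of image features with integrated
    pathway-level (IPL) activity matrices, including a moderated-t
    differential activity test. A synthetic-data module generates
    Beer-Lambert H&E images with known stain ground truth, cohorts with
    planted class/cluster/survival structure, and coupled IPL matrices so
    every stage can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    pROC,
    png,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    limma,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
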