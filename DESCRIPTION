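Package: lipometab
Title: Plasma Metabo-Lipidomics Classification of HCV-Related Liver Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable chemometrics pipeline for discriminating hepatocellular
    carcinoma (HCC) from chronic hepatitis C (HCV) and mixed cryoglobulinemia
    (MC) using plasma metabolomics and lipidomics feature tables. Provides
    quality-control filtering (missingness and QC coefficient-of-variation),
    total-ion-sum and internal-standard normalization, minimum-fraction
    imputation, log10 transformation and autoscaling; per-block PCA with
    Hotelling T2 confidence ellipses and multiblock SUM-PCA low-level fusion;
    deterministic per-class Kennard-Stone train/test splitting on super
    scores; PLS-DA and SIMCA classifiers with leave-one-out component
    selection; VIP-based variable reduction with ROC/AUROC evaluation;
    per-feature univariate statistics and over-representation analysis; and an
    alpha-fetoprotein (AFP) threshold-rule benchmark with cohort contingency
    statistics. A synthetic-cohort generator emulating the study design makes
    the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC,
    withr
Config/testthat/edition: 3
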