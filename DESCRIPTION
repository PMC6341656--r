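Package: cdcn
Title: Cell Line-Drug Complex Network Models for Anticancer Drug
    Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts anticancer drug responses of cell line-drug pairs,
    including pairs where both the cell line and the drug are untested,
    with a kernel-weighted estimator on a bipartite cell line-drug
    network.  Cell lines are connected through Pearson correlation of
    their gene expression profiles and drugs through Tanimoto similarity
    of their molecular fingerprints; every observed response contributes
    to a prediction with a Gaussian kernel weight in both similarity
    layers.  Includes leave-one-out cross-validation, grid search over
    the two kernel bandwidths, per-drug RMSE/NRMSE and correlation
    metrics, sensitive/resistant classification with ROC/AUC, nearest
    neighbour imputation baselines, random-deletion imputation
    benchmarks, and a synthetic data generator with planted cluster
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    yaml
Suggests:
    ape,
    ChemmineR,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
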