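Package: fibrosig
Title: Supervised Gene-Signature Discovery for Lens Wound Healing Versus Fibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for small-n two-class transcriptomic
    biomarker discovery, built around an ex vivo lens injury model in which
    epithelial cells undergo either regenerative wound healing (WH) or
    fibrosis (F). Provides FPKM-to-TPM normalization and log transformation,
    a Welch mean-difference univariate screen, three supervised
    feature-selection tracks (bootstrap-LASSO stability selection with a
    cross-validated sparse refit, linear-SVM coefficient ranking with
    permutation-importance pruning and a calibrated RBF-kernel classifier,
    and random-forest Gini plus permutation importance), held-out
    classifier and per-gene ROC evaluation, pooled log2 fold changes,
    per-candidate-gene set enrichment (weighted Kolmogorov-Smirnov
    enrichment scores with gene-set-permutation NES and FDR), delta-delta-Ct
    qPCR quantification, and a synthetic-data generator that emulates the
    two-condition by three-day by three-replicate design for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    randomForest,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
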