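Package: crossnorm
Title: Cross-Platform Transcriptomic Normalization with Non-Differentially
    Expressed Reference Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training gene-expression classifiers on one
    transcriptomic platform (e.g., RNA-seq) and testing them on another
    (e.g., microarray). Implements per-gene one-way ANOVA selection of
    differentially expressed genes (features) and non-differentially
    expressed genes (normalization references), nine normalization schemes
    including reference-based quantile normalization (RQN), percentile
    mapping onto a reference distribution, and internal-control-gene
    scaling, a stratified cross-platform train/test protocol with repeated
    evaluation, and imbalance-aware metrics (Cohen's kappa, balanced
    accuracy, and the composite Evalue). A synthetic two-platform data
    generator with known ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    ranger,
    xgboost,
    glmnet,
    nnet
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC
Config/testthat/edition: 3
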