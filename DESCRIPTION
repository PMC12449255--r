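Package: scpoem
Title: Co-Embedding of scATAC-Seq Peaks and scRNA-Seq Genes for Peak-Gene
    Regulatory Linking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Jointly embeds chromatin-accessibility peaks and expressed genes
    from paired single-cell multiome data into one low-dimensional space.
    A heterogeneous network of peak-peak co-accessibility (binarize, embed,
    KNN metacells, windowed graphical lasso), gene-gene principal-component
    regression, and peak-gene regression (lasso, random forest, XGBoost) is
    turned into row-stochastic transition matrices; weighted training node
    pairs are sampled along the meta-path scheme P3-P2-P1-G1-G2-G3 and a
    skip-gram model with negative sampling learns the shared embedding.
    Embedded Euclidean distance ranks candidate cis-regulatory peak-gene
    relationships; downstream tools provide gene subgrouping with assigned
    peak sets, differential-regulation scoring between conditions by
    manifold alignment, subsample-stability checks, and a synthetic paired
    multiome generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    dplyr,
    ggplot2,
    glmnet,
    generics,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    methods,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    uwot,
    jsonlite,
    optparse,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
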