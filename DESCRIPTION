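Package: nmfsubtypes
Title: Molecular Subtyping of Bulk Expression Data by Non-Smooth NMF
    Consensus Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and validation of molecular subtypes from bulk
    gene-expression matrices. Implements non-smooth non-negative matrix
    factorisation (nsNMF) with consensus clustering and cophenetic rank
    selection, entropy-based informative-gene signature extraction,
    cross-dataset transfer of cluster membership by regularised linear
    discriminant analysis with bootstrap stability assessment, a
    SMOTE-balanced cross-validated logistic-classifier framework for
    signature validation, and cluster-phenotype association statistics
    (chi-square tests of independence, ANCOVA with Tukey post-hoc tests,
    Shapiro-Wilk-gated log transformation). A negative-binomial
    synthetic-data generator with planted cluster signatures makes the
    whole pipeline testable without access-restricted cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    cluster,
    glmnet,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
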