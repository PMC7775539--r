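Package: crossgp
Title: Genomic Prediction of Crossbred Pig Performance from Purebred and
    Crossbred SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting crossbred pig feed efficiency (residual
    feed intake) and growth rate (average daily gain) from purebred and
    crossbred SNP genotypes. Provides a pedigree-aware simulator of
    three-way crossbreeding populations with additive and dominance QTL and
    a tunable purebred-crossbred genetic correlation; phenotype preparation
    (test-window filtering, multivariate outlier removal, residual feed
    intake derivation, environmental pre-adjustment, sire averaging); SNP
    and sample quality control with near-zero-variance and correlation-based
    feature pruning; epsilon-insensitive support vector regression with a
    Gaussian kernel and GBLUP with a VanRaden genomic relationship matrix
    and REML or Gibbs variance components; and a nested cross-validation
    evaluation design with within-fold Spearman feature selection,
    purebred/crossbred training-testing scenarios, IN/OUT-of-training sire
    partitioning, generational splits, and bootstrap rank-correlation
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
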