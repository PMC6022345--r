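Package: pleiogwas
Title: Joint Analysis of Two GWAS Cohorts by a Four-Group Spike-and-Slab Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Joint Bayesian analysis of two genome-wide association studies
    collected on different cohorts, leveraging pleiotropy through a four-group
    spike-and-slab model on per-SNP association statuses. Model fitting uses a
    variational Bayesian EM algorithm with closed-form coordinate updates for
    quantitative traits and a Bohning quadratic bound for case-control traits
    with fixed-effect covariates. Provides local false discovery rates with
    direct-posterior-probability global FDR control, polygenic risk prediction,
    a likelihood-ratio test for pleiotropy, a simulation engine with
    AR-correlated Hardy-Weinberg genotypes and liability-threshold case-control
    sampling, benchmarking utilities, and PLINK bed/bim/fam input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
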