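Package: methresponse
Title: Longitudinal Methylome and Genetic Analysis of Treatment Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal DNA methylation and genetic
    association studies of treatment response, of the kind used to study
    dimethyl fumarate therapy in relapsing-remitting multiple sclerosis.
    Provides reference-free cell-type deconvolution of beta-value matrices by
    constrained alternating least squares with bootstrap selection of the
    number of cell types, paired per-CpG differential-methylation modelling
    with probe filters and volcano classification, relative-risk co-membership
    clustering of gene sets with an oxidative-stress overlap score, and
    SNP association testing with genotype quality control, exact
    Hardy-Weinberg testing and principal-component stratification correction.
    A synthetic-data module generates all inputs with known planted structure
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust,
    cluster,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
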