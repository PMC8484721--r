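Package: virophylo
Title: Phylogenetic Mixed Models for Cross-Species Viral Load
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating how host evolutionary relatedness shapes the
    outcome of virus infection across host species. Implements an end-to-end
    analysis from raw qPCR cycle-threshold tables (plate-effect correction,
    delta-delta-Ct fold changes, melt-curve exclusion rules) to a multi-response
    phylogenetic generalized linear mixed model fitted by Gibbs sampling with
    parameter-expanded covariance priors. Posterior summaries include
    phylogenetic heritability, repeatability, between-virus interspecific
    correlations with highest-posterior-density intervals and pMCMC values, and
    back-transformed mean fold changes. A synthetic-data generator produces
    ultrametric host trees, Kronecker-structured species-level traits, and
    Ct-level experiments with plate and technical-replicate structure, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
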