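Package: gsmix
Title: Bayesian Polygenic and Multi-Marker Mixture Models for Genomic
    Selection
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gibbs samplers for the polygenic animal model, a Bayesian
    multi-marker regression model with truncated-normal scaling factors and
    two-component mixture priors on marker effects, and the combined
    marker-plus-pedigree model. Includes pedigree additive relationship
    matrices with sparse inverses, variance-component and heritability
    summaries, within- and between-family cross-validation with predictive
    ability, prior-to-posterior odds (PPOR) marker evidence classification,
    and a simulator for full-sib family populations with cage effects and
    LD-bearing SNP panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
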