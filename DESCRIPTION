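Package: muqtl
Title: Mixture-of-Uniforms Shrinkage Priors for QTL Mapping and Genomic
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian variable selection for quantitative-trait mapping and
    genomic prediction using a mixture-of-uniforms (MU) spike-and-slab prior
    on SNP effects. Provides a single-site Gibbs sampler and a generalized
    EM (GEM) fixed-point estimator for the marker regression model with an
    optional full-sib family effect, Bayes-factor based QTL inference with
    Kass-Raftery evidence categories, prior calibration of the
    hyper-parameters via expected heritability, genomic estimated breeding
    values with cross-validation machinery, sure independence screening,
    and a pedigree-aware population simulator with known true breeding
    values for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
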