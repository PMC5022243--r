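Package: imprintgp
Title: Bayesian Genomic Prediction with Dominance and Genomic Imprinting
    Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genomic prediction from phased SNP genotypes using Bayesian
    mixture models that partition genetic variance into additive, dominance
    and parent-of-origin (genomic imprinting) components. Provides a
    synthetic phased-population simulator with litter structure, quality
    control for phased genotype data, additive/dominance/imprinting design
    matrix codings, a Gibbs sampler with a four-component normal mixture
    prior on SNP effects and ordered class variances, variance-component and
    heritability decomposition, pseudo-Bayes-factor model comparison via
    conditional predictive ordinates, and hold-out validation of genomic
    breeding values (reliability, Hotelling-Williams tests, bias regression).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
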