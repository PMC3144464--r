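Package: bayesalphabet
Title: Bayesian Alphabet Whole-Genome Regression for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome regression for genomic prediction with the Bayesian
    alphabet of marker-effect models: BayesA and BayesB with fixed prior
    inclusion probability, and BayesCpi and BayesDpi which treat the prior
    probability that a SNP has zero effect as unknown. Includes single-site
    Gibbs and Metropolis-Hastings samplers with compiled inner loops,
    pedigree BLUP and genomic BLUP (ridge-regression) baselines, genotype
    quality control, forward-in-time population simulators (a linkage
    equilibrium scenario and a drift-mutation-recombination scenario),
    and evaluation tools for genomic estimated breeding values, posterior
    QTL counts and sliding-window genetic variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
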