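Package: seedspan
Title: Comparative Seed Longevity Analysis Under Controlled Ageing
Version: 0.1.0
Authors@R:
    person("Seedspan", "Developers", email = "seedspan@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of seed longevity from
    controlled-ageing germination trials. Fits seed viability decline
    curves (probit form of the viability equation and a negative
    logistic alternative) to germination time-courses and estimates the
    time to 50 percent of initial viability (p50) with delta-method
    standard errors. Builds dated phylogenies from a taxonomy plus a
    node-age table (BLADJ-style even interpolation), extracts
    phylogenetic covariance matrices, and quantifies phylogenetic
    signal with Pagel's lambda, Blomberg's K and the Fritz-Purvis D
    statistic for binary traits. Explains log10 p50 by seed traits
    with maximum-likelihood GLS and phylogenetic GLS, small-sample AIC
    model selection, Akaike weights and full model averaging, plus
    one-way ANOVA and Tukey HSD group comparisons. A synthetic-data
    module generates germination time-courses, Brownian-motion traits,
    threshold binary characters and complete study-like datasets with
    known ground truth. Ships a 39-species calcareous-grassland p50
    dataset as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
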