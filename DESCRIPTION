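Package: pollendiv
Title: Pollen-Host Trait Coding and Trait-Dependent Diversification in Bees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for linking quantitative pollen-load data to
    macroevolutionary diversification in bees. Codes per-sample pollen
    counts into binary host-accessibility and host-specificity characters,
    reconstructs ancestral states under a two-state Markov model with
    Bayesian node posteriors and per-node Bayes factors, fits
    state-dependent speciation-extinction (BiSSE/HiSSE-style) models with
    hidden states and incomplete taxon sampling by multi-start maximum
    likelihood and by Bayesian MCMC, and provides forward simulators of
    trees, characters and synthetic pollen tables for power,
    false-positive and sampling-sensitivity studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
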