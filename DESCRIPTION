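Package: ploidyshift
Title: Comparative Phylogenetics of Haplodiploidy and Chromosome Number
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the macroevolution of haplodiploid
    reproduction on time-calibrated phylogenies. Implements one- and
    two-rate continuous-time Markov models of the diplodiploid to
    haplodiploid transition with AICc model comparison over tree sets,
    stochastic character mapping with origin counting, maximum-likelihood
    Brownian-motion ancestral reconstruction of (log) chromosome number,
    a Monte Carlo test of whether haplodiploidy originates at nodes with
    low ancestral chromosome numbers, Bayesian phylogenetic and taxonomic
    mixed models with MCMC significance reporting, and Felsenstein's
    liability threshold model. Includes matched tree/trait ingestion with
    genus- and family-level tip matching, and generators of synthetic
    birth-death trees and jointly evolving discrete/continuous traits
    with recorded ground-truth histories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    phangorn,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
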