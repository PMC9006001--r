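Package: epochsse
Title: Epoch-Sliced Binary-State Diversification, Ancestral Reconstruction
    and Stochastic Character Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse how a binary trait and geological time jointly
    shape diversification on time-calibrated phylogenies. Implements the
    binary-state speciation and extinction (BiSSE) likelihood with rates that
    are piecewise-constant across geological epochs, a nested ladder of
    constrained rate models selected by stepwise likelihood-ratio testing, a
    slice-sampling MCMC for posterior rate summaries pooled across a sample of
    trees, maximum-likelihood Brownian-motion ancestral reconstruction of a
    continuous trait with optional fossil constraints (traitgrams), stochastic
    character mapping of binary traits, and forward simulators (state- and
    epoch-dependent birth-death trees, Markov traits, Brownian traits, toy
    fossil tables) so every stage can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
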