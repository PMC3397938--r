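Package: mkasr
Type: Package
Title: Bayesian Ancestral State Reconstruction of Discrete Characters
    by Reversible-Jump MCMC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ancestral state reconstruction for discrete morphological
    characters on phylogenies under continuous-time Markov (Mk) models.
    Implements the kappa branch-length power transform, reversible-jump
    Markov chain Monte Carlo over the four rate-model configurations of a
    binary character, a hierarchical exponential prior on transition rates,
    integration over a posterior sample of trees, and marginal state
    probabilities at nodes addressed as most recent common ancestors of
    taxon sets.  A synthetic-data module generates tree samples and
    simulated characters with known parameters so that every stage of the
    pipeline can be validated without access to empirical tree samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Matrix,
    phangorn,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
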