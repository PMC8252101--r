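Package: mycotroph
Title: Symbiont Switching and Trophic-Mode Evolution on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-phylogenetic analysis of discrete trait evolution for
    mycoheterotrophic plants and their fungal symbionts. Provides continuous-time
    Markov chain (Mk/ARD) likelihoods on dated trees via Felsenstein pruning,
    constrained rate matrices, maximum-likelihood fitting, Pagel's lambda for
    discrete characters, ancestral-state reconstruction by stochastic character
    mapping with endpoint-conditioned path sampling, Bayesian MultiState MCMC
    with reversible-jump model averaging, stepping-stone marginal likelihoods
    and Bayes factors, Pagel's correlated-evolution (Discrete) test, a
    constrained coupled-character hypothesis suite compared by BIC, trait-coding
    utilities for orchid mycorrhizal association and trophic-mode data, and a
    synthetic-data generator with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    Matrix,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
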