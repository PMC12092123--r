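Package: PreySpec
Title: Phylogenetic Prey Specificity and Allometry of Spider Venom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of venom potency on a time-calibrated
    phylogeny. Converts qualitative and quantitative diet reports into
    normalized diet profiles, computes the diet-weighted divergence time
    between an assay model organism and a predator's natural prey
    (the prey-specificity statistic D_LD50-Diet, in hundreds of millions
    of years), converts body length to mass by a power law and estimates
    allometric scaling exponents, fits Bayesian phylogenetic ("animal")
    mixed models by Gibbs sampling with phylogenetic heritability and
    Gelman-Rubin convergence diagnostics, performs maximum-likelihood
    ancestral state estimation for binary traits under the Mk model, and
    simulates complete datasets with known ground truth for parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
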