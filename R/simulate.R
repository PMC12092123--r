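## Synthetic data with known ground truth, mirroring the generative
## assumptions of the analysis: a Yule predator phylogeny, Dirichlet diet
## compositions over the 12 prey classes, log10 LD50 linear in the
## prey-specificity statistic with phylogenetic + species + residual
## variance components, venom yield scaling as mass^0.75, and a binary
## silk-use trait evolving under an ER Mk process.

## Deterministic sub-seed derivation: adding a component never perturbs the
## streams of the others.  Kept below 2^31 - 1.
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}

#' Default ground-truth parameters for synthetic datasets
#'
#' Effect sizes and variance components used by [simulateVenomData()]:
#' a prey-specificity slope `betaD = 0.4` on the log10 LD50 scale per Hmya,
#' route intercept shifts of +2.01 (thorax/cephalothorax) and +1.01
#' (abdomen) relative to IP, null mass and silk effects, variance
#' components (animal 0.2, species 0.1, residual 0.2), a yield scaling
#' exponent of 0.75 with lognormal noise, and an Mk rate of 0.003
#' transitions per Myr for silk use.
#'
#' @return named list of generating parameters.
#' @export
defaultGroundTruth <- function() {
  list(beta0 = 0.5, betaD = 0.4, betaMass = 0, betaSilk = 0,
       routeContrasts = c(IP = 0, IV = 0, SC = 0,
                          thorax_cephalothorax = 2.01, abdomen = 1.01),
       sigma2Animal = 0.2, sigma2Species = 0.1, sigma2Resid = 0.2,
       yieldExponent = 0.75, yieldIntercept = -0.8, yieldNoiseSd = 0.3,
       mkRate = 0.003)
}

#' Simulate a Yule (pure-birth) calibrated tree
#'
#' @param nTips number of tips (>= 2).
#' @param seed integer RNG seed; the same seed always reproduces the same
#'   newick text.
#' @param rootDepth depth to rescale the tree to, in Myr (default 300).
#' @return an ultrametric [CalibratedPhylogeny-class] with tips
#'   `sp_001, sp_002, ...`.
#' @export
simulateTree <- function(nTips, seed, rootDepth = 300) {
  if (nTips < 2) psDomainError("need at least 2 tips")
  set.seed(seed)
  phy <- ape::rphylo(nTips, birth = 1, death = 0)
  d <- max(ape::node.depth.edgelength(phy)[seq_len(nTips)])
  phy$edge.length <- phy$edge.length * rootDepth / d
  phy$tip.label <- sprintf("sp_%03d", seq_len(nTips))
  new("CalibratedPhylogeny", tree = phy)
}

#' Simulate diet profiles over the prey classes
#'
#' Each species receives a random subset of prey classes — Insecta is always
#' included, reflecting the insect-dominated diets of spiders — of size
#' `1 + Poisson(3)` capped at the number of classes (median richness 4),
#' with symmetric-Dirichlet weights at the given concentration.
#'
#' @param species character vector of predator species names.
#' @param preyTaxa candidate prey taxa (default [preyClasses()]).
#' @param concentration Dirichlet concentration (default 1; large values
#'   approach uniform weights).
#' @param seed integer RNG seed.
#' @return named list of [DietProfile-class] objects.
#' @export
simulateDiets <- function(species, preyTaxa = preyClasses(),
                          concentration = 1, seed = 1) {
  if (!length(preyTaxa)) psDomainError("need at least one prey taxon")
  set.seed(seed)
  base <- if ("Insecta" %in% preyTaxa) "Insecta" else preyTaxa[1]
  out <- lapply(species, function(sp) {
    k <- min(length(preyTaxa), 1 + stats::rpois(1, 3))
    taxa <- unique(c(base, sample(setdiff(preyTaxa, base),
                                  max(0, k - 1))))
    g <- stats::rgamma(length(taxa), shape = concentration, rate = 1)
    ## guard against an all-zero gamma draw at tiny concentrations
    if (sum(g) == 0) g <- rep(1, length(taxa))
    keep <- g > 1e-12 * sum(g)
    w <- g[keep] / sum(g[keep])
    new("DietProfile", species = sp, weights = stats::setNames(w, taxa[keep]))
  })
  stats::setNames(out, species)
}

#' Simulate species trait table
#'
#' Body lengths are lognormal (median 12 mm), masses follow
#' [lengthToMass()], silk use evolves on the tree under the ER Mk process at
#' `truth$mkRate`, and extraction methods are drawn uniformly.
#'
#' @param x a [CalibratedPhylogeny-class].
#' @param truth ground-truth list (see [defaultGroundTruth()]).
#' @param seed integer RNG seed.
#' @return data.frame with one row per tip.
#' @export
simulateTraits <- function(x, truth = defaultGroundTruth(), seed = 1) {
  silk <- simulateBinaryTrait(x, truth$mkRate, seed = .subSeed(seed, 7))
  set.seed(seed)
  sp <- tipLabels(x)
  len <- stats::rlnorm(length(sp), meanlog = log(12), sdlog = 0.5)
  data.frame(species = sp,
             body_length_mm = len,
             body_mass_g = lengthToMass(len),
             silk_use = as.logical(silk[sp]),
             venom_yield_mg = NA_real_,
             extraction_method = sample(c("electrical_stimulation",
                                          "direct_stimulation",
                                          "gland_extraction"),
                                        length(sp), replace = TRUE),
             vertebrate_in_diet = NA,
             stringsAsFactors = FALSE)
}

#' Simulate LD50 assay records under the animal model
#'
#' For each species with a diet profile, draws 1-5 assays (mean 2.4) with
#' random model organisms and injection routes, computes the
#' prey-specificity statistic D on the reference tree, and generates
#' `log10 LD50 = beta0 + betaD * D + betaMass * log10(mass) + betaSilk * silk
#' + route contrast + a + s + e`, where `a` is multivariate normal with
#' covariance `sigma2Animal * A` over species, and `s`, `e` are iid normal.
#'
#' @param x predator [CalibratedPhylogeny-class].
#' @param diets named list of [DietProfile-class] (subset of tips).
#' @param traits trait table from [simulateTraits()].
#' @param truth ground-truth list.
#' @param seed integer RNG seed.
#' @param refTree prey reference tree (default [preyReferenceTree()]).
#' @param models candidate model organisms.
#' @return data.frame of assay records with the generating `d_ld50_diet_hmya`
#'   column included.
#' @export
simulateLD50 <- function(x, diets, traits, truth = defaultGroundTruth(),
                         seed = 1, refTree = preyReferenceTree(),
                         models = defaultModelOrganisms()) {
  set.seed(seed)
  sp <- names(diets)
  q <- length(sp)
  A <- phyloCorrelationMatrix(x, sp)
  aEff <- if (truth$sigma2Animal > 0)
    drop(t(chol(A)) %*% stats::rnorm(q)) * sqrt(truth$sigma2Animal)
  else rep(0, q)
  sEff <- stats::rnorm(q, 0, sqrt(truth$sigma2Species))
  names(aEff) <- names(sEff) <- sp

  tr <- traits[match(sp, traits$species), ]
  rows <- lapply(seq_along(sp), function(i) {
    n <- sample(1:5, 1, prob = c(0.3, 0.3, 0.2, 0.1, 0.1))
    mod <- sample(models, n, replace = TRUE)
    rt <- sample(names(truth$routeContrasts), n, replace = TRUE,
                 prob = c(0.4, 0.15, 0.2, 0.15, 0.1))
    D <- vapply(mod, function(m)
      specificity(dLD50Diet(refTree, diets[[i]], m)), numeric(1))
    mu <- truth$beta0 + truth$betaD * D +
      truth$betaMass * log10(tr$body_mass_g[i]) +
      truth$betaSilk * as.numeric(tr$silk_use[i]) +
      truth$routeContrasts[rt] +
      aEff[i] + sEff[i]
    y <- mu + stats::rnorm(n, 0, sqrt(truth$sigma2Resid))
    data.frame(species = sp[i], model_organism = mod,
               ld50_mg_per_kg = 10^y, route = rt, lyophilized = TRUE,
               d_ld50_diet_hmya = unname(D), log10_ld50 = unname(y),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Simulate venom yields scaling with body mass
#'
#' `log10 yield = intercept + exponent * log10(mass) + Normal(0, noiseSd^2)`.
#'
#' @param traits trait table with positive `body_mass_g`.
#' @param exponent allometric scaling exponent (default 0.75).
#' @param intercept log10 yield at 1 g (default -0.8).
#' @param noiseSd lognormal noise SD on the log10 scale (default 0.3).
#' @param seed integer RNG seed.
#' @param nMeasures total measurements; species are recycled so some carry
#'   repeats (default one per species).
#' @return data.frame with `species`, `body_mass_g`, `venom_yield_mg`.
#' @export
simulateYield <- function(traits, exponent = 0.75, intercept = -0.8,
                          noiseSd = 0.3, seed = 1,
                          nMeasures = nrow(traits)) {
  if (any(traits$body_mass_g <= 0, na.rm = TRUE) || all(is.na(traits$body_mass_g)))
    psDomainError("positive body masses are required")
  set.seed(seed)
  idx <- rep_len(seq_len(nrow(traits)), nMeasures)
  m <- traits$body_mass_g[idx]
  y <- intercept + exponent * log10(m) + stats::rnorm(nMeasures, 0, noiseSd)
  data.frame(species = traits$species[idx], body_mass_g = m,
             venom_yield_mg = 10^y, stringsAsFactors = FALSE)
}

#' Simulate a binary trait under the ER Mk process
#'
#' The root state is a fair coin; along each branch of length `t` the state
#' flips with probability `(1 - exp(-2*rate*t)) / 2`.
#'
#' @param x a [CalibratedPhylogeny-class].
#' @param rate transition rate per Myr (>= 0).
#' @param seed integer RNG seed.
#' @return named integer vector of 0/1 tip states.
#' @export
simulateBinaryTrait <- function(x, rate, seed = 1) {
  if (rate < 0) psDomainError("rate must be >= 0")
  set.seed(seed)
  phy <- x@tree
  ntip <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  state <- integer(ntip + phy$Nnode)
  state[ntip + 1L] <- stats::rbinom(1, 1, 0.5)
  for (k in rev(seq_len(nrow(po$edge)))) {     # pre-order: root to tips
    u <- po$edge[k, 1]; v <- po$edge[k, 2]
    pflip <- (1 - exp(-2 * rate * po$edge.length[k])) / 2
    flip <- stats::rbinom(1, 1, pflip)
    state[v] <- if (flip) 1L - state[u] else state[u]
  }
  stats::setNames(state[seq_len(ntip)], phy$tip.label)
}

#' Simulate a complete comparative venom dataset
#'
#' Assembles tree, traits, diets, LD50 assays and yield measurements with
#' the default study shape: 75 species, diets and LD50 assays for 64 of
#' them (1-5 assays each, about 153 records), and 60 yield measurements
#' over 47 species.  Component RNG streams are derived deterministically
#' from the master seed, so regenerating with the same seed is
#' bit-reproducible and adding one component never perturbs the others.
#'
#' @param nSpecies total species on the tree.
#' @param seed master integer seed.
#' @param truth ground-truth list (see [defaultGroundTruth()]).
#' @param nLD50Species species with diet + LD50 data.
#' @param nYieldSpecies species with yield data.
#' @param nYieldMeasures total yield measurements.
#' @param concentration diet Dirichlet concentration.
#' @return a [SyntheticDataset-class].
#' @export
simulateVenomData <- function(nSpecies = 75, seed = 1,
                              truth = defaultGroundTruth(),
                              nLD50Species = 64, nYieldSpecies = 47,
                              nYieldMeasures = 60, concentration = 1) {
  phy <- simulateTree(nSpecies, seed = .subSeed(seed, 1))
  traits <- simulateTraits(phy, truth, seed = .subSeed(seed, 2))

  set.seed(.subSeed(seed, 3))
  ld50Sp <- sort(sample(tipLabels(phy), min(nLD50Species, nSpecies)))
  yieldSp <- sort(sample(tipLabels(phy), min(nYieldSpecies, nSpecies)))

  diets <- simulateDiets(ld50Sp, concentration = concentration,
                         seed = .subSeed(seed, 4))
  assays <- simulateLD50(phy, diets, traits, truth, seed = .subSeed(seed, 5))
  yields <- simulateYield(traits[match(yieldSp, traits$species), ],
                          exponent = truth$yieldExponent,
                          intercept = truth$yieldIntercept,
                          noiseSd = truth$yieldNoiseSd,
                          seed = .subSeed(seed, 6),
                          nMeasures = nYieldMeasures)
  ## vertebrate prey flag follows the simulated diet
  vert <- c("Osteichthyes", "Amphibia", "Squamata", "Aves", "Mammalia")
  traits$vertebrate_in_diet <- vapply(traits$species, function(sp) {
    if (!sp %in% names(diets)) return(NA)
    any(names(dietWeights(diets[[sp]])) %in% vert)
  }, logical(1))

  new("SyntheticDataset", phylogeny = phy, diets = diets, traits = traits,
      assays = assays, yields = yields, truth = truth,
      seed = as.integer(seed))
}

#' Write a synthetic dataset to a directory
#'
#' Emits the same plain-text formats the readers consume: `tree.nwk`,
#' `traits.csv`, `assays.csv`, `diet_profiles.csv` (species, prey_taxon,
#' weight), `yields.csv` and `truth.yml`.  Output is byte-deterministic for
#' a given dataset.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeVenomData <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("tree.nwk", "traits.csv", "assays.csv",
                            "diet_profiles.csv", "yields.csv", "truth.yml"))
  writeNewick(dataset@phylogeny, paths[1])
  utils::write.csv(dataset@traits, paths[2], row.names = FALSE)
  assayCols <- c("species", "model_organism", "ld50_mg_per_kg", "route",
                 "lyophilized")
  utils::write.csv(dataset@assays[, assayCols], paths[3], row.names = FALSE)
  dp <- do.call(rbind, lapply(dataset@diets, function(p)
    data.frame(species = speciesName(p), prey_taxon = names(dietWeights(p)),
               weight = unname(dietWeights(p)), stringsAsFactors = FALSE)))
  utils::write.csv(dp, paths[4], row.names = FALSE)
  utils::write.csv(dataset@yields, paths[5], row.names = FALSE)
  yaml::write_yaml(dataset@truth, paths[6])
  invisible(paths)
}
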