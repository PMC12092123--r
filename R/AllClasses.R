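#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib PreySpec, .registration = TRUE
NULL

setOldClass("phylo")

#' Time-calibrated rooted phylogeny
#'
#' Wraps an [ape::read.tree()] `phylo` object whose branch lengths are in
#' millions of years (Myr).  Divergence-time operations additionally require
#' the tree to be ultrametric (all root-to-tip path lengths equal within a
#' relative tolerance of 1e-6), which is checked on demand by
#' [isUltrametric()] rather than at construction, since non-ultrametric trees
#' are still valid inputs for topology-only work.
#'
#' @slot tree an `ape::phylo` object, rooted, with branch lengths (Myr).
#' @seealso [readNewick()], [divergenceTime()], [phyloCorrelationMatrix()]
#' @exportClass CalibratedPhylogeny
setClass("CalibratedPhylogeny", representation(tree = "phylo"))

setValidity("CalibratedPhylogeny", function(object) {
  phy <- object@tree
  msgs <- character(0)
  if (is.null(phy$edge.length))
    msgs <- c(msgs, "tree has no branch lengths")
  else if (any(phy$edge.length < 0))
    msgs <- c(msgs, "negative branch lengths")
  if (anyDuplicated(phy$tip.label))
    msgs <- c(msgs, sprintf("duplicate tip labels: %s",
                            paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
                                  collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Qualitative diet report
#'
#' Literature diet description for one predator species: each prey taxon
#' carries one of the four ordinal abundance labels
#' (`major`, `common`, `uncommon`, `rare`).
#'
#' @slot species predator species name.
#' @slot labels named character vector, prey taxon -> label.
#' @exportClass QualitativeDietReport
setClass("QualitativeDietReport",
         representation(species = "character", labels = "character"))

setValidity("QualitativeDietReport", function(object) {
  bad <- setdiff(unique(object@labels), names(dietLabelScores()))
  if (length(bad))
    sprintf("labels outside vocabulary: %s", paste(bad, collapse = ", "))
  else if (length(object@labels) && is.null(names(object@labels)))
    "labels must be named by prey taxon"
  else TRUE
})

#' Quantitative diet report
#'
#' Proportions of prey taxa in one predator's diet, as reported by a
#' quantitative study.  The total may fall short of 1 when part of the diet
#' was recorded as unidentified "other" items.
#'
#' @slot species predator species name.
#' @slot proportions named numeric vector in `[0, 1]`, prey taxon -> proportion.
#' @exportClass QuantitativeDietReport
setClass("QuantitativeDietReport",
         representation(species = "character", proportions = "numeric"))

setValidity("QuantitativeDietReport", function(object) {
  p <- object@proportions
  if (length(p) && is.null(names(p))) return("proportions must be named by prey taxon")
  if (any(p < 0 | p > 1)) return("each proportion must lie in [0, 1]")
  if (sum(p) > 1 + 0.01) return(sprintf("proportions sum to %.3f > 1.01", sum(p)))
  TRUE
})

#' Normalized diet profile
#'
#' Final per-species diet composition: positive weights over prey taxa that
#' sum to 1 (within the +/- 0.01 slack that the scoring procedure allows for
#' display-rounded published tables).  These weights are the ones used when
#' averaging divergence times in [dLD50Diet()].
#'
#' @slot species predator species name.
#' @slot weights named numeric vector, prey taxon -> weight in (0, 1].
#' @slot rank named character vector of taxonomic ranks (class/superclass/order),
#'   possibly empty.
#' @exportClass DietProfile
setClass("DietProfile",
         representation(species = "character", weights = "numeric",
                        rank = "character"),
         prototype(rank = character(0)))

setValidity("DietProfile", function(object) {
  w <- object@weights
  if (!length(w)) return("profile has no prey taxa")
  if (is.null(names(w))) return("weights must be named by prey taxon")
  if (any(w <= 0)) return("all weights must be > 0")
  if (abs(sum(w) - 1) > 0.01 + 1e-9)
    return(sprintf("weights sum to %.4f, outside 1 +/- 0.01", sum(w)))
  TRUE
})

#' Prey-specificity statistic result
#'
#' The diet-weighted mean divergence time (Hmya, hundreds of millions of
#' years) between an assay model organism and a predator's natural prey,
#' together with the per-prey contributions it is assembled from.
#'
#' @slot species predator species.
#' @slot model assay model organism.
#' @slot D the statistic (Hmya, >= 0).
#' @slot contributions data.frame with columns `taxon`, `weight`,
#'   `divergence_hmya`.
#' @exportClass PreySpecificityResult
setClass("PreySpecificityResult",
         representation(species = "character", model = "character",
                        D = "numeric", contributions = "data.frame"))

setValidity("PreySpecificityResult", function(object) {
  ct <- object@contributions
  need <- c("taxon", "weight", "divergence_hmya")
  if (!all(need %in% names(ct))) return("contributions missing columns")
  d <- sum(ct$weight * ct$divergence_hmya)
  if (abs(d - object@D) > 1e-9) return("D does not equal the weight-sum of contributions")
  if (object@D < min(ct$divergence_hmya) - 1e-12 ||
      object@D > max(ct$divergence_hmya) + 1e-12)
    return("D outside the range of contribution divergences")
  TRUE
})

#' Log-log power-law fit
#'
#' @slot exponent slope on the log10-log10 scale.
#' @slot intercept log10 of the multiplicative coefficient.
#' @slot ci numeric(2), 95% confidence interval for the exponent.
#' @slot se standard error of the exponent.
#' @slot n number of observations.
#' @exportClass PowerLawFit
setClass("PowerLawFit",
         representation(exponent = "numeric", intercept = "numeric",
                        ci = "numeric", se = "numeric", n = "integer"))

setValidity("PowerLawFit", function(object) {
  if (length(object@ci) != 2) return("ci must have length 2")
  if (object@exponent < object@ci[1] - 1e-12 || object@exponent > object@ci[2] + 1e-12)
    return("interval does not contain the point estimate")
  TRUE
})

#' Phylogenetic mixed-model specification
#'
#' Declarative description of one Gaussian animal-model fit: the response,
#' fixed-effect terms (interactions written `"a:b"`), which random terms to
#' include (`"animal"` = phylogenetic effect with covariance proportional to
#' the relatedness matrix, `"species"` = iid repeat-measure effect), the
#' reference level of each categorical term, the inverse-gamma priors on the
#' variance components, and the chain settings.
#'
#' @slot response name of the response column.
#' @slot fixed character vector of fixed-effect terms.
#' @slot random subset of `c("animal", "species")`.
#' @slot referenceLevels named list, categorical column -> reference level.
#' @slot priors named list with elements `animal`, `species`, `residual`,
#'   each `c(shape =, scale =)` for the inverse-gamma prior.
#' @slot iterations,burnin,thin,nChains integer chain settings.
#' @slot seed integer RNG seed; chain `k` uses `seed + k - 1`.
#' @exportClass ModelSpec
setClass("ModelSpec",
         representation(response = "character", fixed = "character",
                        random = "character", referenceLevels = "list",
                        priors = "list", iterations = "integer",
                        burnin = "integer", thin = "integer",
                        nChains = "integer", seed = "integer"))

setValidity("ModelSpec", function(object) {
  msgs <- character(0)
  if (object@burnin >= object@iterations) msgs <- c(msgs, "burnin must be < iterations")
  if (object@thin < 1L) msgs <- c(msgs, "thin must be >= 1")
  if (object@nChains < 1L) msgs <- c(msgs, "nChains must be >= 1")
  if (!all(object@random %in% c("animal", "species")))
    msgs <- c(msgs, "random terms must be a subset of {animal, species}")
  for (nm in c("animal", "species", "residual")) {
    pr <- object@priors[[nm]]
    if (is.null(pr) || length(pr) != 2 || any(pr <= 0))
      msgs <- c(msgs, sprintf("prior '%s' must be positive c(shape, scale)", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' Posterior draws from a phylogenetic mixed model
#'
#' @slot draws list of per-chain matrices (rows = retained draws, columns =
#'   fixed effects then `var_animal`, `var_species`, `var_resid`).
#' @slot spec the [ModelSpec-class] that produced the fit.
#' @slot species species represented in the random terms.
#' @slot nObs number of records fitted.
#' @exportClass PMMFit
setClass("PMMFit",
         representation(draws = "list", spec = "ModelSpec",
                        species = "character", nObs = "integer"))

#' Posterior summary of a phylogenetic mixed model
#'
#' @slot fixed data.frame: `mean`, `lower`, `upper`, `significant`, `rhat`,
#'   `ess` per fixed effect (equal-tailed 95% credibility intervals; a term is
#'   significant when its interval excludes zero).
#' @slot variance data.frame of posterior means for the variance components.
#' @slot h2 named numeric: posterior mean and 95% CI of the phylogenetic
#'   heritability.
#' @slot h2Denominator which variance components form the h2 denominator.
#' @exportClass PosteriorSummary
setClass("PosteriorSummary",
         representation(fixed = "data.frame", variance = "data.frame",
                        h2 = "numeric", h2Denominator = "character"))

#' Maximum-likelihood ancestral state estimate
#'
#' @slot rates fitted transition rate(s), per Myr (`q` for ER;
#'   `q01`, `q10` for ARD).
#' @slot logLik maximized log-likelihood.
#' @slot marginals matrix of marginal state probabilities, one row per
#'   internal node (rownames are `node_<number>` or the node label), columns
#'   `state0`, `state1`.
#' @slot model `"ER"` or `"ARD"`.
#' @exportClass AncestralEstimate
setClass("AncestralEstimate",
         representation(rates = "numeric", logLik = "numeric",
                        marginals = "matrix", model = "character"))

setValidity("AncestralEstimate", function(object) {
  if (any(object@rates < 0)) return("rates must be >= 0")
  s <- rowSums(object@marginals)
  if (any(abs(s - 1) > 1e-9)) return("node probabilities must sum to 1")
  TRUE
})

#' Synthetic comparative dataset with known ground truth
#'
#' @slot phylogeny the simulated predator phylogeny.
#' @slot diets named list of [DietProfile-class] objects.
#' @slot traits species-level trait table.
#' @slot assays LD50 assay records (one row per measurement).
#' @slot yields venom-yield measurements.
#' @slot truth named list of generating parameters.
#' @slot seed integer master seed.
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
         representation(phylogeny = "CalibratedPhylogeny", diets = "list",
                        traits = "data.frame", assays = "data.frame",
                        yields = "data.frame", truth = "list",
                        seed = "integer"))
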