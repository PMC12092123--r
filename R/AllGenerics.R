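#' Extract the underlying `phylo` object
#' @param x a `CalibratedPhylogeny`.
#' @return an `ape::phylo` object.
#' @export
setGeneric("asPhylo", function(x) standardGeneric("asPhylo"))

#' @rdname asPhylo
setMethod("asPhylo", "CalibratedPhylogeny", function(x) x@tree)

#' Tip labels of a phylogeny
#' @param x a `CalibratedPhylogeny`.
#' @return character vector of tip labels.
#' @export
setGeneric("tipLabels", function(x) standardGeneric("tipLabels"))

#' @rdname tipLabels
setMethod("tipLabels", "CalibratedPhylogeny", function(x) x@tree$tip.label)

#' Number of tips
#' @param x a `CalibratedPhylogeny`.
#' @export
setGeneric("nTips", function(x) standardGeneric("nTips"))

#' @rdname nTips
setMethod("nTips", "CalibratedPhylogeny", function(x) length(x@tree$tip.label))

#' Species name stored in an object
#' @param x a package object carrying a species field.
#' @export
setGeneric("speciesName", function(x) standardGeneric("speciesName"))

#' @rdname speciesName
setMethod("speciesName", "DietProfile", function(x) x@species)
#' @rdname speciesName
setMethod("speciesName", "QualitativeDietReport", function(x) x@species)
#' @rdname speciesName
setMethod("speciesName", "QuantitativeDietReport", function(x) x@species)
#' @rdname speciesName
setMethod("speciesName", "PreySpecificityResult", function(x) x@species)

#' Diet weights of a profile
#' @param x a `DietProfile`.
#' @return named numeric vector of full-precision weights.
#' @export
setGeneric("dietWeights", function(x) standardGeneric("dietWeights"))

#' @rdname dietWeights
setMethod("dietWeights", "DietProfile", function(x) x@weights)

#' Prey-specificity statistic value
#' @param x a `PreySpecificityResult`.
#' @return the statistic in Hmya.
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))

#' @rdname specificity
setMethod("specificity", "PreySpecificityResult", function(x) x@D)

#' Per-prey contributions to the statistic
#' @param x a `PreySpecificityResult`.
#' @return data.frame with `taxon`, `weight`, `divergence_hmya`.
#' @export
setGeneric("contributions", function(x) standardGeneric("contributions"))

#' @rdname contributions
setMethod("contributions", "PreySpecificityResult", function(x) x@contributions)

#' Posterior draws
#'
#' @param x a `PMMFit`.
#' @param combine if `TRUE` (default) rbind all chains into one matrix,
#'   otherwise return the per-chain list.
#' @return matrix or list of matrices of retained draws.
#' @export
setGeneric("posteriorDraws", function(x, combine = TRUE) standardGeneric("posteriorDraws"))

#' @rdname posteriorDraws
setMethod("posteriorDraws", "PMMFit", function(x, combine = TRUE) {
  if (combine) do.call(rbind, x@draws) else x@draws
})

#' Ground truth of a synthetic dataset
#' @param x a `SyntheticDataset`.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname groundTruth
setMethod("groundTruth", "SyntheticDataset", function(x) x@truth)

setMethod("show", "CalibratedPhylogeny", function(object) {
  phy <- object@tree
  d <- max(ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)])
  cat(sprintf("CalibratedPhylogeny: %d tips, depth %.4g Myr, %s\n",
              length(phy$tip.label), d,
              if (isUltrametric(object)) "ultrametric" else "not ultrametric"))
})

setMethod("show", "DietProfile", function(object) {
  cat(sprintf("DietProfile for %s (%d prey taxa)\n", object@species,
              length(object@weights)))
  w <- displayedWeights(object)
  print(w)
  cat(sprintf("displayed total: %.3f\n", sum(w)))
})

setMethod("show", "PreySpecificityResult", function(object) {
  cat(sprintf("D_LD50-Diet: %.4f Hmya  (%s vs model %s, %d prey taxa)\n",
              object@D, object@species, object@model, nrow(object@contributions)))
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit: exponent %.4f [%.4f, %.4f], coefficient %.4g, n = %d\n",
              object@exponent, object@ci[1], object@ci[2],
              10^object@intercept, object@n))
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s ~ %s\n", object@response,
              if (length(object@fixed)) paste(object@fixed, collapse = " + ") else "1"))
  cat(sprintf("  random: %s\n",
              if (length(object@random)) paste(object@random, collapse = " + ") else "(none)"))
  cat(sprintf("  chains: %d x %d iterations (burn-in %d, thin %d), seed %d\n",
              object@nChains, object@iterations, object@burnin, object@thin,
              object@seed))
})

setMethod("show", "PMMFit", function(object) {
  nd <- vapply(object@draws, nrow, integer(1))
  cat(sprintf("PMMFit: %d chain(s), %s retained draws each, %d observations, %d species\n",
              length(object@draws), paste(unique(nd), collapse = "/"),
              object@nObs, length(object@species)))
})

setMethod("show", "PosteriorSummary", function(object) {
  cat("Posterior summary (equal-tailed 95% CIs; '*' = interval excludes 0)\n")
  fx <- object@fixed
  fx$sig <- ifelse(fx$significant, "*", "")
  print(fx[, c("mean", "lower", "upper", "sig", "rhat", "ess")], digits = 4)
  cat("\nVariance components (posterior means):\n")
  print(object@variance, digits = 4)
  cat(sprintf("\nh2 = %.3f [%.3f, %.3f]  (denominator: %s)\n",
              object@h2["mean"], object@h2["lower"], object@h2["upper"],
              object@h2Denominator))
})

setMethod("show", "AncestralEstimate", function(object) {
  cat(sprintf("AncestralEstimate (%s model): rate(s) %s /Myr, logLik %.4f, %d internal nodes\n",
              object@model, paste(signif(object@rates, 4), collapse = ", "),
              object@logLik, nrow(object@marginals)))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset (seed %d): %d species, %d diet profiles, %d assays, %d yield measures\n",
              object@seed, nTips(object@phylogeny), length(object@diets),
              nrow(object@assays), nrow(object@yields)))
})
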