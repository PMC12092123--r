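## Divergence times and the diet-weighted prey-specificity statistic.
##
## Taxa are resolved against the tree in three steps: exact tip match
## (case-insensitive, spaces/underscores interchangeable), then internal
## node (clade) label, yielding the clade's tip set.  Divergence between two
## taxa is the age of their most recent common ancestor; overlapping tip
## sets (a model organism inside its own prey clade) give 0, because at the
## class/order resolution of diet data within-clade distances are not
## observable.

.resolveTaxon <- function(x, taxon) {
  phy <- x@tree
  key <- normalizeName(taxon)
  tips <- normalizeName(phy$tip.label)
  hit <- which(tips == key)
  if (length(hit)) return(hit)
  if (!is.null(phy$node.label)) {
    nl <- normalizeName(phy$node.label)
    nhit <- which(nl == key)
    if (length(nhit) == 1) {
      node <- length(phy$tip.label) + nhit
      cl <- ape::extract.clade(phy, node)$tip.label
      return(match(cl, phy$tip.label))
    }
  }
  psLookupError(sprintf("taxon '%s' matches no tip or clade label on the tree", taxon),
                taxon = taxon)
}

.nodeAges <- function(x) {
  phy <- x@tree
  dist <- ape::node.depth.edgelength(phy)
  max(dist[seq_along(phy$tip.label)]) - dist
}

.mrcaAgeTips <- function(x, tipsA, tipsB) {
  if (length(intersect(tipsA, tipsB))) return(0)
  phy <- x@tree
  tips <- unique(c(tipsA, tipsB))
  mrca <- if (length(tips) == 1) tips else ape::getMRCA(phy, tips)
  .nodeAges(x)[mrca]
}

#' Divergence time between two taxa (Hmya)
#'
#' Time since the most recent common ancestor of `taxonA` and `taxonB` on an
#' ultrametric calibrated tree, reported in hundreds of millions of years
#' (Hmya).  Taxa may be tips or named clades (internal node labels); a taxon
#' contained in the other's clade diverges at time 0.  Setting
#' `type = "patristic"` instead returns the tip-to-tip path length (twice the
#' MRCA age on an ultrametric tree), for sensitivity analyses.
#'
#' @param x a [CalibratedPhylogeny-class]; must be ultrametric.
#' @param taxonA,taxonB taxon names (tips or clade labels).
#' @param type `"mrca_age"` (default) or `"patristic"`.
#' @return divergence in Hmya (branch lengths are Myr; the result is divided
#'   by 100).
#' @examples
#' phy <- readNewick("((A:100,B:100):200,C:300);")
#' divergenceTime(phy, "A", "B")  # 1 Hmya
#' divergenceTime(phy, "A", "C")  # 3 Hmya
#' @export
divergenceTime <- function(x, taxonA, taxonB, type = c("mrca_age", "patristic")) {
  type <- match.arg(type)
  if (!isUltrametric(x))
    psDomainError("tree is not ultrametric; divergence times are undefined")
  if (normalizeName(taxonA) == normalizeName(taxonB)) return(0)
  ta <- .resolveTaxon(x, taxonA)
  tb <- .resolveTaxon(x, taxonB)
  age <- .mrcaAgeTips(x, ta, tb)
  if (type == "patristic") age <- 2 * age
  age / 100
}

#' Prey-specificity statistic D_LD50-Diet
#'
#' The diet-weighted mean divergence time (Hmya) between the organism used
#' to measure a predator's venom potency and the predator's natural prey:
#' profile weights are renormalized to sum exactly 1, each prey taxon
#' contributes its weight times its divergence from the model organism, and
#' the statistic is the sum of contributions.  Small values mean potency was
#' assayed on something close to what the predator actually eats.
#'
#' @param x reference [CalibratedPhylogeny-class] carrying prey taxa and
#'   model organisms; must be ultrametric.
#' @param profile a [DietProfile-class].
#' @param model model organism name (tip or clade on `x`).
#' @param type divergence convention, see [divergenceTime()].
#' @return a [PreySpecificityResult-class].
#' @examples
#' phy <- readNewick("((A:100,B:100):200,C:300);")
#' pr <- normalizeProfile(c(A = 0.5, C = 0.5), "toy predator")
#' specificity(dLD50Diet(phy, pr, "B"))  # 0.5*1 + 0.5*3 = 2 Hmya
#' @export
dLD50Diet <- function(x, profile, model, type = c("mrca_age", "patristic")) {
  type <- match.arg(type)
  w <- dietWeights(profile)
  w <- w / sum(w)
  div <- vapply(names(w), function(tx) divergenceTime(x, model, tx, type = type),
                numeric(1))
  ct <- data.frame(taxon = names(w), weight = unname(w),
                   divergence_hmya = unname(div), stringsAsFactors = FALSE)
  new("PreySpecificityResult", species = speciesName(profile), model = model,
      D = sum(ct$weight * ct$divergence_hmya), contributions = ct)
}
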