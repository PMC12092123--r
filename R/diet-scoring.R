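#' Qualitative diet label scores
#'
#' The four-level vocabulary used to convert qualitative literature
#' descriptions of a prey taxon's contribution into provisional diet
#' proportions: a prey item described as a major component of the diet
#' scores 0.60, common 0.20, uncommon 0.05 and rare 0.01.
#'
#' @return named numeric vector of default scores.
#' @export
dietLabelScores <- function() {
  c(major = 0.60, common = 0.20, uncommon = 0.05, rare = 0.01)
}

#' Score a qualitative diet label
#'
#' @param label character vector of labels from
#'   `c("major", "common", "uncommon", "rare")`.
#' @return numeric vector of scores (0.60, 0.20, 0.05, 0.01 respectively).
#' @examples
#' scoreLabel("major")   # 0.60
#' scoreLabel("rare")    # 0.01
#' @export
scoreLabel <- function(label) {
  scores <- dietLabelScores()
  bad <- setdiff(unique(label), names(scores))
  if (length(bad))
    psVocabularyError(sprintf("unknown diet label(s): %s", paste(bad, collapse = ", ")),
                      label = bad[1])
  unname(scores[label])
}

#' Construct a qualitative diet report
#' @param species predator species name.
#' @param labels named character vector, prey taxon -> label.
#' @return a [QualitativeDietReport-class].
#' @export
qualitativeDietReport <- function(species, labels = character(0)) {
  new("QualitativeDietReport", species = species, labels = labels)
}

#' Construct a quantitative diet report
#' @param species predator species name.
#' @param proportions named numeric vector, prey taxon -> proportion in `[0, 1]`.
#' @return a [QuantitativeDietReport-class].
#' @export
quantitativeDietReport <- function(species, proportions = numeric(0)) {
  new("QuantitativeDietReport", species = species, proportions = proportions)
}

#' Combine qualitative and quantitative diet reports
#'
#' Merges the two report types for one predator species into the "unweighted
#' combined estimate": a prey taxon with a quantitative proportion keeps that
#' value; a taxon with only a qualitative label receives a score for its
#' label.  With `calibrate = TRUE` (the default) the label scores are
#' calibrated within the species: when some taxon carries both a label `L`
#' and a quantitative value, every qualitative-only taxon labelled `L` uses
#' that value (the mean when several taxa qualify) instead of the
#' [dietLabelScores()] default.  This reflects the convention that a
#' co-reported quantitative study pins down what, e.g., "common" means for
#' that particular spider.  With `calibrate = FALSE` the defaults are always
#' used.
#'
#' The result typically sums to more than 1 and is normalized by
#' [normalizeProfile()].
#'
#' @param qual a [QualitativeDietReport-class] (may be empty).
#' @param quant a [QuantitativeDietReport-class] (may be empty), or a plain
#'   named numeric estimates map (useful when re-applying the operation to
#'   its own output).
#' @param calibrate use within-species label calibration (default `TRUE`).
#' @return named numeric vector of unweighted diet estimates.
#' @examples
#' q <- qualitativeDietReport("Amaurobius similis",
#'        c(Coleoptera = "common", Dermaptera = "common"))
#' p <- quantitativeDietReport("Amaurobius similis", c(Coleoptera = 0.21))
#' combineReports(q, p)   # Dermaptera calibrated to 0.21
#' @export
combineReports <- function(qual, quant, calibrate = TRUE) {
  if (is.numeric(quant)) {
    qv <- quant
  } else {
    stopifnot(is(quant, "QuantitativeDietReport"))
    qv <- quant@proportions
    if (length(qual@labels) && length(qv) &&
        normalizeName(qual@species) != normalizeName(quant@species))
      psValidationError(sprintf("reports refer to different species: '%s' vs '%s'",
                                qual@species, quant@species))
  }
  stopifnot(is(qual, "QualitativeDietReport"))
  labels <- qual@labels
  taxa <- union(names(labels), names(qv))
  if (!length(taxa))
    psValidationError("both reports are empty")

  ## within-species calibration: label -> mean quantitative value among taxa
  ## carrying both a label and a proportion
  calib <- dietLabelScores()
  if (calibrate) {
    both <- intersect(names(labels), names(qv))
    if (length(both)) {
      for (L in unique(labels[both])) {
        vals <- qv[both[labels[both] == L]]
        calib[L] <- mean(vals)
      }
    }
  }
  est <- vapply(taxa, function(tx) {
    if (tx %in% names(qv)) qv[[tx]]
    else unname(calib[labels[[tx]]])
  }, numeric(1))
  names(est) <- taxa
  est[est > 0]
}

#' Normalize unweighted diet estimates into a diet profile
#'
#' Divides each estimate by the total so the weights sum to 1 (the "weighted
#' combined estimate").  Weights are stored at full floating precision;
#' 3-decimal rounding is display-only (see [displayedWeights()]).
#'
#' @param estimates named numeric vector of unweighted estimates (> 0; zero
#'   entries are dropped).
#' @param species predator species name.
#' @param rank optional named character vector of taxonomic ranks.
#' @return a [DietProfile-class].
#' @export
normalizeProfile <- function(estimates, species = "unknown",
                             rank = character(0)) {
  estimates <- estimates[!is.na(estimates) & estimates > 0]
  total <- sum(estimates)
  if (!length(estimates) || total <= 0)
    psDomainError("all diet estimates are zero; nothing to normalize")
  new("DietProfile", species = species, weights = estimates / total,
      rank = rank)
}

#' Display-rounded diet weights
#'
#' Published diet-composition tables in this literature print weights to
#' three decimals under a convention this function reproduces: weights of at
#' least 0.01 are truncated toward zero at the requested number of decimals
#' (so 0.21/1.45 = 0.14483 displays as 0.144), while trace weights below
#' 0.01 are rounded to nearest (so a 1%-of-1.45 contribution displays as
#' 0.007 rather than being biased down to 0.006).  Stored weights are never
#' rounded; this affects display only.
#'
#' @param x a [DietProfile-class].
#' @param digits decimals to display.
#' @return named numeric vector of displayed weights.
#' @export
displayedWeights <- function(x, digits = 3) {
  w <- x@weights
  f <- 10^digits
  disp <- ifelse(w >= 0.01,
                 trunc(w * f + 1e-9) / f,
                 round(w, digits))
  names(disp) <- names(w)
  disp
}

#' Diet class richness
#'
#' Counts the distinct prey taxonomic classes represented (with positive
#' weight) in a diet profile, mapping each prey taxon to its class through
#' `classMap`.  The universe of prey classes has 12 members, so counts above
#' 12 indicate a corrupt map and raise an error.
#'
#' @param profile a [DietProfile-class].
#' @param classMap named character vector (prey taxon -> class) or a
#'   data.frame with columns `prey_taxon` and `class`.
#' @return integer count in `[1, 12]`.
#' @export
dietClassRichness <- function(profile, classMap) {
  if (is.data.frame(classMap)) {
    cm <- classMap$class
    names(cm) <- classMap$prey_taxon
    classMap <- cm
  }
  names(classMap) <- normalizeName(names(classMap))
  taxa <- names(dietWeights(profile))
  key <- normalizeName(taxa)
  unmapped <- taxa[!key %in% names(classMap)]
  if (length(unmapped))
    psMappingError(sprintf("prey taxon/taxa without a class mapping: %s",
                           paste(unmapped, collapse = ", ")),
                   taxon = unmapped[1])
  n <- length(unique(classMap[key]))
  if (n > 12L)
    psDomainError(sprintf("diet spans %d classes; the prey class universe has 12", n))
  as.integer(n)
}

#' Copy a diet profile to a congeneric species
#'
#' Species with no usable diet data are sometimes assigned the diet of a
#' close relative.  This is an explicit, user-driven copy: the donor profile
#' must be named, and no automatic inference is performed.
#'
#' @param profile donor [DietProfile-class].
#' @param species recipient species name.
#' @return a [DietProfile-class] for the recipient.
#' @export
inheritDiet <- function(profile, species) {
  new("DietProfile", species = species, weights = profile@weights,
      rank = profile@rank)
}

#' Build diet profiles from a validated diet-report table
#'
#' Convenience wrapper: splits a `diet_reports` table (see [readTable()]) by
#' species, assembles the per-species qualitative and quantitative reports,
#' and runs [combineReports()] + [normalizeProfile()].
#'
#' @param reports data.frame from `readTable(..., "diet_reports")`.
#' @param calibrate passed to [combineReports()].
#' @return named list of [DietProfile-class] objects.
#' @export
profilesFromReports <- function(reports, calibrate = TRUE) {
  out <- lapply(split(reports, reports$species), function(df) {
    ql <- df$qual_label[!is.na(df$qual_label)]
    names(ql) <- df$prey_taxon[!is.na(df$qual_label)]
    qp <- df$quant_proportion[!is.na(df$quant_proportion)]
    names(qp) <- df$prey_taxon[!is.na(df$quant_proportion)]
    rk <- character(0)
    if (any(!is.na(df$rank))) {
      rk <- df$rank
      names(rk) <- df$prey_taxon
      rk <- rk[!is.na(rk)]
    }
    est <- combineReports(qualitativeDietReport(df$species[1], ql),
                          quantitativeDietReport(df$species[1], qp),
                          calibrate = calibrate)
    normalizeProfile(est, species = df$species[1], rank = rk)
  })
  out
}
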