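## Packaged reference calibration for prey classes and model organisms.
## This tree is a synthetic stand-in for a literature-derived divergence-time
## calibration: its topology and depths are loosely patterned on published
## metazoan timescales (root at 700 Myr) and it is intended for simulation
## and illustration, not as an authoritative set of divergence times.

.psCache <- new.env(parent = emptyenv())

#' Synthetic prey-class reference tree
#'
#' An ultrametric tree over the 12 prey taxonomic classes that occur in
#' spider diets (each class is a labelled clade) plus the common assay model
#' organisms (mouse, rat, house fly, cricket, cockroach, waxmoth, honeybee)
#' as tips.  Divergence times between a model organism and a prey class are
#' read off this tree by [divergenceTime()]; a model organism inside a prey
#' clade (e.g. a dipteran model against prey "Insecta") diverges at 0.
#'
#' The tree is synthetic: depths follow published metazoan timescales only
#' loosely, and it ships for simulation and worked examples.
#'
#' @return a [CalibratedPhylogeny-class] (root depth 700 Myr).
#' @export
preyReferenceTree <- function() {
  if (is.null(.psCache$refTree)) {
    path <- system.file("extdata", "synthetic_prey_reference.nwk",
                        package = "PreySpec")
    .psCache$refTree <- readNewick(path)
  }
  .psCache$refTree
}

#' The 12 prey taxonomic classes
#' @return character vector of class names resolvable on
#'   [preyReferenceTree()].
#' @export
preyClasses <- function() {
  c("Insecta", "Arachnida", "Malacostraca", "Diplopoda", "Chilopoda",
    "Gastropoda", "Opisthopora", "Osteichthyes", "Amphibia", "Squamata",
    "Aves", "Mammalia")
}

#' Default assay model organisms
#' @return character vector of tip names on [preyReferenceTree()].
#' @export
defaultModelOrganisms <- function() {
  c("Mus_musculus", "Musca_domestica", "Acheta_domesticus",
    "Periplaneta_americana", "Galleria_mellonella")
}

#' Packaged prey-taxon to class map
#' @return data.frame with columns `prey_taxon`, `class` covering the 12
#'   classes and common order-level diet taxa.
#' @export
preyClassMap <- function() {
  readTable(system.file("extdata", "prey_class_map.csv", package = "PreySpec"),
            "taxon_class_map")
}
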