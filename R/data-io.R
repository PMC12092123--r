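#' Read a time-calibrated tree from newick text or a file
#'
#' Parses a rooted newick tree with branch lengths in millions of years and
#' validates the [CalibratedPhylogeny-class] invariants (branch lengths
#' present and non-negative, unique tip labels).  A cheap syntax pre-scan
#' reports the character offset of the first unbalanced parenthesis before
#' handing the string to [ape::read.tree()], so malformed input fails with a
#' located parse error rather than an opaque one.
#'
#' @param x newick string, or path to a file containing one.
#' @return a [CalibratedPhylogeny-class].
#' @examples
#' phy <- readNewick("((A:1,B:1):1,C:2);")
#' tipLabels(phy)
#' @export
readNewick <- function(x) {
  txt <- if (length(x) == 1 && !grepl("\\(", x) && file.exists(x))
    paste(readLines(x, warn = FALSE), collapse = "")
  else paste(x, collapse = "")
  .checkNewickSyntax(txt)
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    psParseError("newick text could not be parsed", offset = NA_integer_)
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup))
    psValidationError(sprintf("duplicate tip labels: %s", paste(dup, collapse = ", ")),
                      duplicates = dup)
  if (is.null(phy$edge.length))
    psValidationError("tree has no branch lengths")
  if (any(phy$edge.length < 0))
    psValidationError("negative branch lengths in tree")
  new("CalibratedPhylogeny", tree = phy)
}

## Balanced-parenthesis scan with 1-based character offsets.
.checkNewickSyntax <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        psParseError(sprintf("unbalanced ')' at character %d", i), offset = i)
    }
  }
  if (depth > 0L)
    psParseError(sprintf("%d unclosed '(' at end of input", depth),
                 offset = length(chars))
  if (!grepl(";\\s*$", txt))
    psParseError("newick text does not end with ';'", offset = length(chars))
  invisible(TRUE)
}

#' Write a tree as newick text
#'
#' Branch lengths are written with enough digits (default 17 significant)
#' that `readNewick(writeNewick(x))` reproduces topology and branch lengths
#' exactly.
#'
#' @param x a [CalibratedPhylogeny-class].
#' @param path optional file path; if `NULL` the newick string is returned.
#' @param digits significant digits for branch lengths (17 guarantees an exact
#'   decimal round trip for doubles).
#' @return the newick string, invisibly when written to a file.
#' @export
writeNewick <- function(x, path = NULL, digits = 17) {
  stopifnot(is(x, "CalibratedPhylogeny"))
  txt <- ape::write.tree(x@tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Check ultrametricity
#'
#' All root-to-tip path lengths must agree within `tol` relative to tree
#' depth.  Divergence-time operations require this.
#'
#' @param x a [CalibratedPhylogeny-class].
#' @param tol relative tolerance.
#' @return logical.
#' @export
isUltrametric <- function(x, tol = 1e-6) {
  phy <- x@tree
  d <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  diff(range(d)) <= tol * max(d)
}

#' Root-to-tip depth of an ultrametric tree (Myr)
#' @param x a [CalibratedPhylogeny-class].
#' @return maximum root-to-tip distance.
#' @export
treeDepth <- function(x) {
  phy <- x@tree
  max(ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)])
}

## ---------------------------------------------------------------------------
## Tabular schemas.  All tables are comma-separated, UTF-8, "." decimal.

.routeLevels <- c("IP", "IV", "SC", "thorax_cephalothorax", "abdomen")
.extractionLevels <- c("electrical_stimulation", "direct_stimulation",
                       "gland_extraction", "unknown")
.dietRanks <- c("class", "superclass", "order")

.schemas <- list(
  assays = list(
    columns = c(species = "character", model_organism = "character",
                ld50_mg_per_kg = "numeric", route = "character",
                lyophilized = "logical"),
    required = c("species", "model_organism", "ld50_mg_per_kg", "route"),
    enums = list(route = .routeLevels)
  ),
  traits = list(
    columns = c(species = "character", body_length_mm = "numeric",
                body_mass_g = "numeric", silk_use = "logical",
                venom_yield_mg = "numeric", extraction_method = "character",
                vertebrate_in_diet = "logical"),
    required = c("species"),
    enums = list(extraction_method = .extractionLevels)
  ),
  diet_reports = list(
    columns = c(species = "character", prey_taxon = "character",
                rank = "character", qual_label = "character",
                quant_proportion = "numeric"),
    required = c("species", "prey_taxon"),
    enums = list(rank = .dietRanks,
                 qual_label = c("major", "common", "uncommon", "rare"))
  ),
  taxon_class_map = list(
    columns = c(prey_taxon = "character", class = "character"),
    required = c("prey_taxon", "class"),
    enums = list()
  )
)

#' Read and validate a delimited data table
#'
#' Reads a comma-separated file with a header row against one of the
#' registered schemas (`"assays"`, `"traits"`, `"diet_reports"`,
#' `"taxon_class_map"`), coercing column types and checking enumerated
#' values.  Every failure raises a condition of class `psValidationError`
#' whose `row` and `column` fields identify the offending cell (rows are
#' counted in the data, excluding the header).
#'
#' @param path CSV file path.
#' @param schema one of the registered schema names.
#' @return a validated `data.frame`; row numbers are kept in the `.row`
#'   column for downstream error reporting.
#' @export
readTable <- function(path, schema = c("assays", "traits", "diet_reports",
                                       "taxon_class_map")) {
  schema <- match.arg(schema)
  sc <- .schemas[[schema]]
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8",
                         strip.white = TRUE)
  validateTable(raw, schema)
}

#' Validate an in-memory table against a registered schema
#'
#' @param raw data.frame of character columns (as read from CSV) or an
#'   already-typed data.frame.
#' @param schema registered schema name.
#' @return typed, validated data.frame with a `.row` provenance column.
#' @rdname readTable
#' @export
validateTable <- function(raw, schema) {
  sc <- .schemas[[schema]]
  if (is.null(sc)) psDomainError(sprintf("unknown schema '%s'", schema))
  missing <- setdiff(sc$required, names(raw))
  if (length(missing))
    psValidationError(sprintf("missing required column(s): %s",
                              paste(missing, collapse = ", ")),
                      column = missing[1])
  out <- data.frame(.row = seq_len(nrow(raw)))
  for (col in names(sc$columns)) {
    if (!col %in% names(raw)) {
      out[[col]] <- switch(sc$columns[[col]],
                           numeric = NA_real_, logical = NA,
                           NA_character_)
      next
    }
    v <- raw[[col]]
    blank <- !nzchar(trimws(as.character(v))) | is.na(v)
    out[[col]] <- switch(
      sc$columns[[col]],
      numeric = {
        num <- suppressWarnings(as.numeric(as.character(v)))
        bad <- which(!blank & is.na(num))
        if (length(bad))
          psValidationError(sprintf("unparseable numeric '%s' (column %s, row %d)",
                                    v[bad[1]], col, bad[1]),
                            row = bad[1], column = col)
        num
      },
      logical = {
        lg <- .parseLogical(as.character(v))
        bad <- which(!blank & is.na(lg))
        if (length(bad))
          psValidationError(sprintf("unparseable logical '%s' (column %s, row %d)",
                                    v[bad[1]], col, bad[1]),
                            row = bad[1], column = col)
        lg
      },
      as.character(ifelse(blank, NA, as.character(v)))
    )
    allowed <- sc$enums[[col]]
    if (!is.null(allowed)) {
      bad <- which(!is.na(out[[col]]) & !out[[col]] %in% allowed)
      if (length(bad))
        psValidationError(
          sprintf("value '%s' not in {%s} (column %s, row %d)",
                  out[[col]][bad[1]], paste(allowed, collapse = ", "),
                  col, bad[1]),
          row = bad[1], column = col)
    }
  }
  ## schema-specific record invariants
  if (schema == "assays") {
    bad <- which(!is.na(out$ld50_mg_per_kg) & out$ld50_mg_per_kg <= 0)
    if (length(bad))
      psValidationError(sprintf("LD50 must be > 0 (column ld50_mg_per_kg, row %d)", bad[1]),
                        row = bad[1], column = "ld50_mg_per_kg")
    bad <- which(is.na(out$ld50_mg_per_kg))
    if (length(bad))
      psValidationError(sprintf("missing LD50 value (row %d)", bad[1]),
                        row = bad[1], column = "ld50_mg_per_kg")
  }
  if (schema == "traits") {
    for (col in c("body_length_mm", "body_mass_g", "venom_yield_mg")) {
      bad <- which(!is.na(out[[col]]) & out[[col]] <= 0)
      if (length(bad))
        psValidationError(sprintf("%s must be > 0 (row %d)", col, bad[1]),
                          row = bad[1], column = col)
    }
  }
  if (schema == "diet_reports") {
    bad <- which(!is.na(out$quant_proportion) &
                   (out$quant_proportion < 0 | out$quant_proportion > 1))
    if (length(bad))
      psValidationError(sprintf("quant_proportion outside [0, 1] (row %d)", bad[1]),
                        row = bad[1], column = "quant_proportion")
    bad <- which(is.na(out$qual_label) & is.na(out$quant_proportion))
    if (length(bad))
      psValidationError(sprintf("row %d carries neither a qualitative label nor a quantitative proportion",
                                bad[1]),
                        row = bad[1], column = "qual_label")
  }
  out
}

.parseLogical <- function(x) {
  x <- tolower(trimws(x))
  ifelse(x %in% c("true", "t", "1", "yes"), TRUE,
         ifelse(x %in% c("false", "f", "0", "no"), FALSE, NA))
}

#' Read a model configuration from YAML
#'
#' The YAML mirrors [modelSpec()]: top-level keys `response`, `fixed`,
#' `random`, `reference_levels`, `priors` (each component a `[shape, scale]`
#' pair), `iterations`, `burnin`, `thin`, `n_chains`, `seed`.  Unspecified
#' keys fall back to the [modelSpec()] defaults.
#'
#' @param path YAML file path.
#' @return a [ModelSpec-class].
#' @export
readModelConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$response)) psValidationError("config is missing 'response'")
  priors <- NULL
  if (!is.null(cfg$priors))
    priors <- lapply(cfg$priors, function(p) c(shape = p[[1]], scale = p[[2]]))
  args <- list(response = cfg$response,
               fixed = as.character(cfg$fixed %||% character(0)),
               random = as.character(cfg$random %||% c("animal", "species")))
  if (!is.null(cfg$reference_levels)) args$referenceLevels <- cfg$reference_levels
  if (!is.null(priors)) args$priors <- priors
  for (k in c("iterations", "burnin", "thin", "seed"))
    if (!is.null(cfg[[k]])) args[[k]] <- as.integer(cfg[[k]])
  if (!is.null(cfg$n_chains)) args$nChains <- as.integer(cfg$n_chains)
  do.call(modelSpec, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
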