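## Structured error conditions.  Every user-facing validation failure carries
## machine-readable provenance fields (row, column, offset, taxon, ...) so
## callers and tests can locate the offending input without parsing messages.

psCondition <- function(message, class, call = sys.call(-1), ...) {
  structure(
    class = c(class, "psError", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

psStop <- function(message, class, ...) {
  stop(psCondition(message, class, call = sys.call(-1), ...))
}

#' @noRd
psParseError <- function(message, offset = NA_integer_, ...) {
  stop(psCondition(message, "psParseError", offset = offset, ...))
}

#' @noRd
psValidationError <- function(message, row = NA_integer_, column = NA_character_, ...) {
  stop(psCondition(message, "psValidationError", row = row, column = column, ...))
}

#' @noRd
psLookupError <- function(message, taxon = NA_character_, ...) {
  stop(psCondition(message, "psLookupError", taxon = taxon, ...))
}

#' @noRd
psDomainError <- function(message, ...) {
  stop(psCondition(message, "psDomainError", ...))
}

#' @noRd
psVocabularyError <- function(message, label = NA_character_, ...) {
  stop(psCondition(message, "psVocabularyError", label = label, ...))
}

#' @noRd
psMappingError <- function(message, taxon = NA_character_, ...) {
  stop(psCondition(message, "psMappingError", taxon = taxon, ...))
}

## Minimal structured logging to stderr: "LEVEL key=value message".
psLog <- function(level, msg, ...) {
  fields <- list(...)
  kv <- if (length(fields))
    paste(vapply(names(fields), function(k) sprintf("%s=%s", k, fields[[k]]),
                 character(1)), collapse = " ")
  else ""
  message(sprintf("[%s] %s %s", level, msg, kv))
}

## Species-name normalization used everywhere names are matched:
## trim, lower-case, underscores and spaces interchangeable.
normalizeName <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("[ _]+", "_", x)
  tolower(x)
}
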