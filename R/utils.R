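# Shared condition constructors and small helpers.
#
# All user-facing errors carry a subclass so callers (and tests) can
# distinguish format errors from value/configuration/data errors without
# matching message text.

np_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "netpharm_error")))
}

np_assert_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    np_stop("np_value_error", "%s must be finite numeric", what)
  }
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize gene symbols
#'
#' Uppercases and whitespace-trims gene symbols before any set operation,
#' since the upstream sources differ in case conventions.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of normalized symbols; empty strings dropped.
#' @export
normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[nzchar(x) & !is.na(x)]
}

#' Percent yield of an extraction
#'
#' Mass yield of a dried extract relative to the raw material, as a
#' percentage: `100 * extract_mass / material_mass`.
#'
#' @param extract_mass Mass of the dried extract (g).
#' @param material_mass Mass of the raw material (g).
#' @return Yield in percent.
#' @examples
#' extraction_yield(1.68, 10.03) # 16.75 %
#' @export
extraction_yield <- function(extract_mass, material_mass) {
  np_assert_finite(extract_mass, "extract_mass")
  np_assert_finite(material_mass, "material_mass")
  if (any(material_mass <= 0) || any(extract_mass < 0)) {
    np_stop("np_value_error", "masses must be positive")
  }
  100 * extract_mass / material_mass
}

# Read a file path or literal delimited text into a form readr accepts.
# A single-element string without newlines, tabs or commas is a path.
np_read_input <- function(file) {
  if (length(file) == 1 && !grepl("[\n\t,]", file)) {
    if (!file.exists(file)) {
      np_stop("np_io_error", "cannot read input: '%s' does not exist", file)
    }
    return(file)
  }
  if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    return(file)
  }
  I(paste(file, collapse = "\n"))
}
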