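#' Round half away from zero
#'
#' Rounding convention used throughout printed performance tables: halves are
#' rounded away from zero (so 94.15 -> 94.2), unlike base R's banker rounding.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded to \code{digits} decimals.
#' @examples
#' roundHalfAway(c(94.15, -94.15, 2.349), 1)
#' @export
roundHalfAway <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a p-value for reporting
#'
#' Values below 1e-4 are printed as \code{"<0.0001"}, matching the reporting
#' convention of the clinical tables the package reproduces.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
formatPValue <- function(p) {
  ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p))
}

## stable config hash: md5 of the canonical JSON serialisation
configHash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
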