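#' Build a CriteriaSet from a definition list
#'
#' Low-level constructor used by \code{\link{readCriteriaSet}}. The definition
#' mirrors the YAML/JSON schema shipped in
#' \code{system.file("extdata", "criteria", "criteria-schema.json",
#' package = "SLEclassify")}: top-level keys \code{name}, \code{rule_kind},
#' \code{threshold}, \code{threshold_is_strict}, \code{entry},
#' \code{min_clinical}, \code{min_immunologic}, \code{standalone},
#' \code{items} (each with \code{item_id}, \code{predicate}, \code{weight},
#' \code{domain}, \code{category}), \code{probability_transform} and
#' \code{category_cutpoints}.
#'
#' @param def named list conforming to the schema.
#' @return a validated \linkS4class{CriteriaSet}.
#' @export
criteriaSetFromList <- function(def) {
  if (!is.list(def)) stop("definition must be a list", call. = FALSE)
  need <- c("name", "rule_kind", "threshold", "items")
  miss <- setdiff(need, names(def))
  if (length(miss))
    stop(sprintf("criteria definition lacks field(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  items <- def$items
  if (is.data.frame(items)) items <- split(items, seq_len(nrow(items)))
  rows <- lapply(items, function(it) {
    if (is.null(it$item_id) || is.null(it$predicate))
      stop("every item needs 'item_id' and 'predicate'", call. = FALSE)
    data.frame(item_id = as.character(it$item_id),
               predicate = as.character(it$predicate),
               weight = as.numeric(it$weight %||% 1),
               domain = as.character(it$domain %||% NA_character_),
               category = as.character(it$category %||% "none"),
               stringsAsFactors = FALSE)
  })
  itemTab <- do.call(rbind, rows)
  rownames(itemTab) <- NULL
  pt <- def$probability_transform
  if (!is.null(pt)) pt <- list(intercept = as.numeric(pt$intercept),
                               coefficients = unlist(pt$coefficients))
  obj <- new("CriteriaSet",
    name = as.character(def$name),
    ruleKind = as.character(def$rule_kind),
    items = itemTab,
    threshold = as.numeric(def$threshold),
    thresholdStrict = isTRUE(def$threshold_is_strict),
    entry = as.character(def$entry %||% NA_character_),
    minClinical = as.integer(def$min_clinical %||% 0L),
    minImmunologic = as.integer(def$min_immunologic %||% 0L),
    standalone = as.character(unlist(def$standalone) %||% character(0)),
    probabilityTransform = pt,
    categoryCutpoints = as.numeric(def$category_cutpoints %||% c(15, 44, 87))
  )
  .checkCriteriaAnchors(obj)
  obj
}

## Published anchors for the bundled SLERPI definition: the positive weights
## sum to 30.5 and the single negative item is interstitial lung disease at -1.
.checkCriteriaAnchors <- function(x) {
  w <- x@items$weight
  if (identical(toupper(x@name), "SLERPI")) {
    if (!isTRUE(all.equal(sum(w[w > 0]), 30.5)))
      stop(sprintf(
        "SLERPI definition invalid: positive weights sum to %s, expected 30.5",
        sum(w[w > 0])), call. = FALSE)
    neg <- which(w < 0)
    if (length(neg) != 1L || !isTRUE(all.equal(w[neg], -1)))
      stop("SLERPI definition invalid: exactly one item (ILD) must weigh -1",
           call. = FALSE)
  } else if (sum(w < 0) > 1L) {
    stop("at most one item may carry a negative weight", call. = FALSE)
  }
  invisible(x)
}

#' Read a criteria definition file
#'
#' Reads a YAML or JSON criteria definition and returns a validated
#' \linkS4class{CriteriaSet}. Schema violations and predicates referencing
#' features outside the declared vocabulary are errors naming the offending
#' field; a definition named SLERPI whose positive weights do not sum to 30.5
#' is rejected.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a \linkS4class{CriteriaSet}.
#' @examples
#' slerpi <- readCriteriaSet(system.file("extdata", "criteria", "slerpi.yaml",
#'                                       package = "SLEclassify"))
#' sum(itemTable(slerpi)$weight[itemTable(slerpi)$weight > 0])  # 30.5
#' @export
readCriteriaSet <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  def <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  else
    yaml::read_yaml(path)
  criteriaSetFromList(def)
}

#' Bundled criteria definitions
#'
#' The package ships transcriptions of the four criteria sets onto the
#' declared feature vocabulary: the SLERPI simplified score (weighted sum,
#' classify when score > 7, maximum 30.5), ACR-1997 (>= 4 of 11 items),
#' SLICC-2012 (>= 4 of 17 items with >= 1 clinical and >= 1 immunologic, or
#' standalone biopsy-proven nephritis with ANA or anti-dsDNA) and
#' EULAR/ACR-2019 (ANA entry criterion, additive over domains where only the
#' highest-weighted satisfied item per domain counts, classify at >= 10).
#' See the package vignette for the transcription conventions.
#'
#' @param name one or more of \code{"SLERPI"}, \code{"ACR-1997"},
#'   \code{"SLICC-2012"}, \code{"EULAR-ACR-2019"}; default all four.
#' @return a single \linkS4class{CriteriaSet} if one name is given, else a
#'   named list of them.
#' @examples
#' names(bundledCriteria())
#' @export
bundledCriteria <- function(name = c("SLERPI", "ACR-1997", "SLICC-2012",
                                     "EULAR-ACR-2019")) {
  files <- c("SLERPI" = "slerpi.yaml",
             "ACR-1997" = "acr-1997.yaml",
             "SLICC-2012" = "slicc-2012.yaml",
             "EULAR-ACR-2019" = "eular-acr-2019.yaml")
  name <- match.arg(name, several.ok = TRUE)
  out <- lapply(name, function(nm) {
    readCriteriaSet(system.file("extdata", "criteria", files[[nm]],
                                package = "SLEclassify", mustWork = TRUE))
  })
  names(out) <- name
  if (length(out) == 1L) out[[1L]] else out
}
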