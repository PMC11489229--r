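## Predicate mini-language over the feature vocabulary.
##
## A predicate is a character expression combining feature names with
## or(...), and(...), not(...) -- the R operators |, &, ! and parentheses are
## accepted as synonyms. Examples:
##   "or(leucopenia, thrombocytopenia_aiha, anemia)"
##   "and(biopsy_proven_nephritis, or(ana, anti_dsdna))"
## A bare feature name is itself a predicate. Absent features evaluate to 0.

.PRED_CALLS <- c("or", "and", "not", "|", "&", "!", "(")

.parsePredicate <- function(predicate) {
  if (!is.character(predicate) || length(predicate) != 1L || !nzchar(predicate))
    stop("predicate must be a single non-empty string", call. = FALSE)
  expr <- tryCatch(str2lang(predicate), error = function(e)
    stop(sprintf("cannot parse predicate '%s': %s", predicate,
                 conditionMessage(e)), call. = FALSE))
  checkNode <- function(e) {
    if (is.call(e)) {
      fn <- as.character(e[[1L]])
      if (!fn %in% .PRED_CALLS)
        stop(sprintf("disallowed call '%s' in predicate '%s'", fn, predicate),
             call. = FALSE)
      lapply(as.list(e)[-1L], checkNode)
    } else if (!is.symbol(e)) {
      stop(sprintf("predicate '%s' may contain only feature names and or/and/not",
                   predicate), call. = FALSE)
    }
    invisible(NULL)
  }
  checkNode(expr)
  expr
}

#' Feature names referenced by a predicate
#'
#' @param predicate character predicate expression.
#' @return character vector of feature names appearing in the predicate.
#' @examples
#' predicateFeatures("and(biopsy_proven_nephritis, or(ana, anti_dsdna))")
#' @export
predicateFeatures <- function(predicate) {
  all.vars(.parsePredicate(predicate))
}

#' Evaluate a boolean predicate on patient feature data
#'
#' Standard boolean semantics over 0/1 features; a feature that is in the
#' vocabulary but absent from \code{record} is treated as 0 (absent).
#' References to names outside the declared vocabulary are an error.
#'
#' @param predicate character predicate (see package predicate language).
#' @param record a named 0/1 vector (one patient), a features x patients 0/1
#'   matrix, or an \linkS4class{SLECohort}.
#' @return integer 0/1, one value per patient.
#' @examples
#' evaluatePredicate("or(leucopenia, anemia)", c(leucopenia = 1, ana = 0))
#' @export
evaluatePredicate <- function(predicate, record) {
  expr <- .parsePredicate(predicate)
  feats <- all.vars(expr)
  bad <- setdiff(feats, featureVocabulary())
  if (length(bad))
    stop(sprintf("predicate references undeclared feature(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  m <- .featureMatrix(record)
  env <- new.env(parent = emptyenv())
  for (f in feats) {
    v <- if (f %in% rownames(m)) m[f, ] else rep(0L, ncol(m))
    assign(f, v == 1L, envir = env)
  }
  assign("or",  function(...) Reduce(`|`, list(...)), envir = env)
  assign("and", function(...) Reduce(`&`, list(...)), envir = env)
  assign("not", function(x) !x, envir = env)
  assign("|", `|`, envir = env); assign("&", `&`, envir = env)
  assign("!", `!`, envir = env); assign("(", `(`, envir = env)
  as.integer(eval(expr, env))
}

## Canonicalise patient feature input to a features x patients integer matrix.
.featureMatrix <- function(record) {
  if (is(record, "SLECohort"))
    return(assay(record, "features"))
  if (is.matrix(record)) {
    if (is.null(rownames(record)))
      stop("feature matrix must have feature names as rownames", call. = FALSE)
    storage.mode(record) <- "integer"
    return(record)
  }
  if (is.data.frame(record)) {       # patients in rows, features in columns
    feats <- intersect(names(record), featureVocabulary())
    m <- t(as.matrix(record[, feats, drop = FALSE]))
    storage.mode(m) <- "integer"
    if (!is.null(record$id)) colnames(m) <- record$id
    return(m)
  }
  if (is.numeric(record) && !is.null(names(record)))
    return(matrix(as.integer(record), ncol = 1L,
                  dimnames = list(names(record), NULL)))
  stop("record must be a named 0/1 vector, matrix, data.frame or SLECohort",
       call. = FALSE)
}
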