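#' @rdname CriteriaSet-class
#' @param x a \linkS4class{CriteriaSet}.
#' @export
setGeneric("criteriaName", function(x) standardGeneric("criteriaName"))
#' @rdname CriteriaSet-class
#' @export
setGeneric("ruleKind", function(x) standardGeneric("ruleKind"))
#' @rdname CriteriaSet-class
#' @export
setGeneric("itemTable", function(x) standardGeneric("itemTable"))
#' @rdname CriteriaSet-class
#' @export
setGeneric("decisionThreshold", function(x) standardGeneric("decisionThreshold"))

#' @rdname SLECohort-class
#' @param x an \linkS4class{SLECohort}.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname SLECohort-class
#' @export
setGeneric("cohortGroups", function(x) standardGeneric("cohortGroups"))
#' @rdname SLECohort-class
#' @export
setGeneric("polyA", function(x) standardGeneric("polyA"))
#' @rdname SLECohort-class
#' @export
setGeneric("indexDisease", function(x) standardGeneric("indexDisease"))
#' @rdname SLECohort-class
#' @param which subphenotype name: \code{"neuropsychiatric"},
#'   \code{"nephritis"} or \code{"hematological"}.
#' @export
setGeneric("subphenotypeFlag",
           function(x, which) standardGeneric("subphenotypeFlag"))

#' @rdname ConfusionMatrix-class
#' @param x a \linkS4class{ConfusionMatrix}.
#' @export
setGeneric("cmCounts", function(x) standardGeneric("cmCounts"))

#' @rdname RocResult-class
#' @param x a \linkS4class{RocResult}.
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' Apply a criteria set to a cohort
#'
#' Dispatches on the rule kind of \code{criteria} and returns one
#' classification result per patient, order preserved.
#'
#' @param cohort an \linkS4class{SLECohort}, a patients x features 0/1
#'   data.frame (with optional \code{id} column), a features x patients 0/1
#'   matrix, or a single named 0/1 vector.
#' @param criteria a \linkS4class{CriteriaSet}.
#' @return data.frame with columns \code{patient_id}, \code{criteria},
#'   \code{score}, \code{classified}, \code{entry_failed} and, when the set
#'   carries a probability transform, \code{probability_pct} and
#'   \code{category}.
#' @examples
#' rec <- c(ana = 1, immunologic_disorder = 1)
#' applyCriteria(rec, bundledCriteria("SLERPI"))
#' @export
setGeneric("applyCriteria",
           function(cohort, criteria) standardGeneric("applyCriteria"))
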