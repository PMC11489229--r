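## S4 classes for the criteria engine, the cohort container and the
## performance layer.

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

#' CriteriaSet: a declarative rule-based classification criteria set
#'
#' Holds one criteria system as data: an item table (identifier, predicate
#' over the feature vocabulary, weight, domain, clinical/immunologic
#' category), the decision rule kind, the threshold and its strictness, an
#' optional entry predicate (e.g. ANA positivity for EULAR/ACR-2019),
#' minimum clinical/immunologic item counts, standalone rules that classify
#' on their own (the SLICC biopsy-nephritis rule), and an optional logistic
#' probability transform with ordinal category cutpoints.
#'
#' @slot name criteria set name.
#' @slot ruleKind one of \code{"weighted_sum_threshold"},
#'   \code{"count_threshold"}, \code{"domain_weighted_threshold"}.
#' @slot items data.frame with columns \code{item_id}, \code{predicate}
#'   (character expression), \code{weight}, \code{domain}, \code{category}.
#' @slot threshold numeric decision threshold.
#' @slot thresholdStrict logical; \code{TRUE} means classify when score is
#'   strictly greater than the threshold.
#' @slot entry character predicate gating classification, or \code{NA}.
#' @slot minClinical,minImmunologic minimum counts of satisfied clinical /
#'   immunologic items.
#' @slot standalone character vector of predicates, each sufficient alone.
#' @slot probabilityTransform list with \code{intercept} and named
#'   \code{coefficients} (item_id -> coefficient) mapping item indicators to
#'   a probability through the inverse logit, or \code{NULL}.
#' @slot categoryCutpoints numeric ascending percentage cutpoints separating
#'   unlikely/possible/likely/definite.
#'
#' @seealso \code{\link{readCriteriaSet}}, \code{\link{bundledCriteria}},
#'   \code{\link{applyCriteria}}
#' @export
setClass("CriteriaSet",
  representation(
    name = "character",
    ruleKind = "character",
    items = "data.frame",
    threshold = "numeric",
    thresholdStrict = "logical",
    entry = "character",
    minClinical = "integer",
    minImmunologic = "integer",
    standalone = "character",
    probabilityTransform = "listOrNULL",
    categoryCutpoints = "numeric"
  ),
  prototype(
    entry = NA_character_,
    minClinical = 0L,
    minImmunologic = 0L,
    standalone = character(0),
    probabilityTransform = NULL,
    categoryCutpoints = c(15, 44, 87)
  )
)

.validCriteriaSet <- function(object) {
  msg <- character(0)
  kinds <- c("weighted_sum_threshold", "count_threshold",
             "domain_weighted_threshold")
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@ruleKind) != 1L || !object@ruleKind %in% kinds)
    msg <- c(msg, sprintf("'rule_kind' must be one of: %s",
                          paste(kinds, collapse = ", ")))
  it <- object@items
  need <- c("item_id", "predicate", "weight", "domain", "category")
  if (!all(need %in% names(it))) {
    msg <- c(msg, sprintf("items table lacks column(s): %s",
                          paste(setdiff(need, names(it)), collapse = ", ")))
    return(msg)
  }
  if (nrow(it) == 0L) msg <- c(msg, "criteria set has no items")
  if (anyDuplicated(it$item_id))
    msg <- c(msg, "duplicated item_id in items table")
  if (any(!is.finite(it$weight)))
    msg <- c(msg, "all item weights must be finite")
  if (!all(it$category %in% c("clinical", "immunologic", "none")))
    msg <- c(msg, "item category must be clinical, immunologic or none")
  vocab <- featureVocabulary()
  for (p in c(it$predicate, object@standalone,
              if (!is.na(object@entry)) object@entry)) {
    bad <- setdiff(predicateFeatures(p), vocab)
    if (length(bad))
      msg <- c(msg, sprintf(
        "predicate '%s' references undeclared feature(s): %s",
        p, paste(bad, collapse = ", ")))
  }
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    msg <- c(msg, "'threshold' must be a single finite number")
  pt <- object@probabilityTransform
  if (!is.null(pt)) {
    if (!all(c("intercept", "coefficients") %in% names(pt)))
      msg <- c(msg, "probability_transform needs 'intercept' and 'coefficients'")
    else if (!all(names(pt$coefficients) %in% it$item_id))
      msg <- c(msg, "probability_transform coefficients name unknown item_id(s)")
  }
  if (is.unsorted(object@categoryCutpoints, strictly = TRUE) ||
      length(object@categoryCutpoints) != 3L)
    msg <- c(msg, "category_cutpoints must be 3 strictly increasing values")
  if (length(msg)) msg else TRUE
}
setValidity("CriteriaSet", .validCriteriaSet)

#' CohortSpec: parameters of the synthetic case-control cohort generator
#'
#' @slot nCase,nControl group sizes.
#' @slot prevalence list with elements \code{case} and \code{control}, each a
#'   named numeric vector of per-feature Bernoulli prevalences.
#' @slot polyAFreq named numeric, overt-polyautoimmunity frequency per group.
#' @slot controlMix named integer counts of control index diseases; must sum
#'   to \code{nControl}.
#' @slot subphenotypeRule \code{"feature_coupled"} (flags derived from the
#'   corresponding features) or \code{"independent"} (flags drawn at the
#'   printed frequencies, unlinked to features).
#' @slot correlation optional latent Gaussian-copula correlation matrix over
#'   the features (unit diagonal, positive semidefinite), or \code{NULL} for
#'   independent draws.
#' @slot seed integer default seed used when \code{generateCohort} is called
#'   without one.
#'
#' @seealso \code{\link{defaultCohortSpec}}, \code{\link{generateCohort}}
#' @export
setClass("CohortSpec",
  representation(
    nCase = "integer",
    nControl = "integer",
    prevalence = "list",
    polyAFreq = "numeric",
    controlMix = "integer",
    subphenotypeRule = "character",
    correlation = "matrixOrNULL",
    seed = "integer"
  ),
  prototype(subphenotypeRule = "feature_coupled", correlation = NULL,
            seed = 1L)
)

.validCohortSpec <- function(object) {
  msg <- character(0)
  if (object@nCase < 1L || object@nControl < 1L)
    msg <- c(msg, "group sizes must be positive")
  for (g in c("case", "control")) {
    p <- object@prevalence[[g]]
    if (is.null(p)) { msg <- c(msg, sprintf("prevalence lacks '%s'", g)); next }
    if (any(p < 0 | p > 1))
      msg <- c(msg, sprintf("%s prevalences outside [0,1]", g))
    bad <- setdiff(names(p), featureVocabulary())
    if (length(bad))
      msg <- c(msg, sprintf("unknown feature(s) in %s prevalences: %s", g,
                            paste(bad, collapse = ", ")))
  }
  if (any(object@polyAFreq < 0 | object@polyAFreq > 1))
    msg <- c(msg, "polyA frequencies outside [0,1]")
  if (sum(object@controlMix) != object@nControl)
    msg <- c(msg, sprintf(
      "control disease mix sums to %d, not n_control = %d",
      sum(object@controlMix), object@nControl))
  if ("SLE" %in% names(object@controlMix))
    msg <- c(msg, "controls cannot have SLE as index disease")
  if (!object@subphenotypeRule %in% c("feature_coupled", "independent"))
    msg <- c(msg, "subphenotype_rule must be feature_coupled or independent")
  R <- object@correlation
  if (!is.null(R)) {
    feats <- names(object@prevalence$case)
    if (nrow(R) != ncol(R) || !isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
      msg <- c(msg, "correlation matrix must be square and symmetric")
    else {
      if (!isTRUE(all.equal(unname(diag(R)), rep(1, nrow(R)))))
        msg <- c(msg, "correlation matrix must have unit diagonal")
      if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
        msg <- c(msg, "correlation matrix must be positive semidefinite")
      if (nrow(R) != length(feats))
        msg <- c(msg, "correlation dimension must match the feature list")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("CohortSpec", .validCohortSpec)

#' SLECohort: a case-control cohort of binary clinical features
#'
#' Extends \linkS4class{SummarizedExperiment}: the single assay
#' \code{"features"} is a features x patients 0/1 integer matrix over the
#' declared vocabulary; \code{colData} carries \code{group}
#' (\code{case}/\code{control}), \code{polyA}, \code{index_disease}, the
#' three subphenotype flags, ages and sex. Validity enforces binary feature
#' values, that controls never have SLE as index disease, and that
#' subphenotype flags are confined to cases.
#'
#' @seealso \code{\link{generateCohort}}, \code{\link{readCohortCsv}}
#' @export
setClass("SLECohort", contains = "SummarizedExperiment")

.validSLECohort <- function(object) {
  msg <- character(0)
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  m <- assay(object, "features")
  if (!all(m %in% c(0L, 1L)))
    msg <- c(msg, "feature values must all be 0 or 1")
  bad <- setdiff(rownames(m), featureVocabulary())
  if (length(bad))
    msg <- c(msg, sprintf("undeclared feature row(s): %s",
                          paste(bad, collapse = ", ")))
  cd <- colData(object)
  need <- c("group", "polyA", "index_disease", .SUBPHENOTYPES)
  miss <- setdiff(need, names(cd))
  if (length(miss))
    return(c(msg, sprintf("colData lacks column(s): %s",
                          paste(miss, collapse = ", "))))
  if (!all(cd$group %in% c("case", "control")))
    msg <- c(msg, "group must be 'case' or 'control'")
  ctrl <- cd$group == "control"
  if (any(ctrl & !is.na(cd$index_disease) & cd$index_disease == "SLE"))
    msg <- c(msg, "controls cannot have index disease SLE")
  for (s in .SUBPHENOTYPES)
    if (any(ctrl & cd[[s]] == 1L))
      msg <- c(msg, sprintf("subphenotype flag '%s' set on a control", s))
  if (length(msg)) msg else TRUE
}
setValidity("SLECohort", .validSLECohort)

#' ConfusionMatrix: 2x2 classification counts
#'
#' @slot tp,fn,fp,tn nonnegative integer cell counts (rows: truth, columns:
#'   prediction).
#' @seealso \code{\link{confusionMatrix}}, \code{\link{diagnosticMetrics}}
#' @export
setClass("ConfusionMatrix",
  representation(tp = "integer", fn = "integer", fp = "integer",
                 tn = "integer"))

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@tp, object@fn, object@fp, object@tn)
  if (any(is.na(v)) || any(v < 0L)) "cell counts must be nonnegative" else TRUE
})

#' RocResult: an empirical ROC curve with AUC
#'
#' @slot thresholds decreasing score cutoffs (positive means score >= cutoff).
#' @slot tpr,fpr operating points in [0,1], one per threshold.
#' @slot auc area under the curve (trapezoid rule; equals the scaled
#'   Mann-Whitney statistic under the midrank tie convention).
#' @slot aucCI optional confidence interval for the AUC (DeLong).
#' @slot operatingPoint optional named list marking a cutoff on the curve.
#' @seealso \code{\link{rocCurve}}
#' @export
setClass("RocResult",
  representation(thresholds = "numeric", tpr = "numeric", fpr = "numeric",
                 auc = "numeric", aucCI = "numeric",
                 operatingPoint = "listOrNULL"),
  prototype(aucCI = numeric(0), operatingPoint = NULL))

setValidity("RocResult", function(object) {
  msg <- character(0)
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc outside [0,1]")
  if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
    msg <- c(msg, "curve must be nondecreasing in (fpr, tpr)")
  if (length(msg)) msg else TRUE
})
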