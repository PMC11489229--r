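#' Ordinal diagnostic probability category
#'
#' Maps an SLE probability percentage onto the ordinal scale
#' unlikely/possible/likely/definite. The published ranges (0-14, 15-43,
#' 44-86, 87-100) are implemented as the half-open partition [0,15), [15,44),
#' [44,87), [87,100] so that every percentage, including fractional ones,
#' maps to exactly one category.
#'
#' @param probability_pct numeric vector of percentages in [0, 100].
#' @param cutpoints ascending interior cutpoints, default \code{c(15, 44, 87)}.
#' @return factor with levels \code{unlikely < possible < likely < definite}.
#' @examples
#' probabilityCategory(c(99.98, 2.12, 44, 14.999))
#' @export
probabilityCategory <- function(probability_pct, cutpoints = c(15, 44, 87)) {
  if (any(is.na(probability_pct)) ||
      any(probability_pct < 0 | probability_pct > 100))
    stop("probability_pct must lie in [0, 100]", call. = FALSE)
  cut(probability_pct, breaks = c(-Inf, cutpoints, Inf), right = FALSE,
      labels = c("unlikely", "possible", "likely", "definite"),
      ordered_result = TRUE)
}

## items x patients logical matrix of satisfied predicates
.predicateMatrix <- function(criteria, fmat) {
  it <- criteria@items
  P <- vapply(it$predicate, function(p) evaluatePredicate(p, fmat) == 1L,
              logical(ncol(fmat)))
  P <- matrix(P, nrow = ncol(fmat), dimnames = list(NULL, it$item_id))
  t(P)  # items x patients
}

.classify <- function(score, criteria) {
  if (criteria@thresholdStrict) score > criteria@threshold
  else score >= criteria@threshold
}

.categoryCounts <- function(criteria, P) {
  it <- criteria@items
  clin <- colSums(P[it$category == "clinical", , drop = FALSE])
  imm  <- colSums(P[it$category == "immunologic", , drop = FALSE])
  list(clinical = clin, immunologic = imm)
}

.scoreWeightedSum <- function(fmat, criteria) {
  P <- .predicateMatrix(criteria, fmat)
  score <- as.numeric(criteria@items$weight %*% P)
  out <- data.frame(score = score,
                    classified = as.integer(.classify(score, criteria)),
                    entry_failed = 0L)
  pt <- criteria@probabilityTransform
  if (!is.null(pt)) {
    eta <- pt$intercept +
      as.numeric(pt$coefficients %*% P[names(pt$coefficients), , drop = FALSE])
    out$probability_pct <- 100 * plogis(eta)
    out$category <- probabilityCategory(out$probability_pct,
                                        criteria@categoryCutpoints)
  }
  out
}

.scoreCountThreshold <- function(fmat, criteria) {
  P <- .predicateMatrix(criteria, fmat)
  score <- colSums(P)
  cc <- .categoryCounts(criteria, P)
  base <- .classify(score, criteria) &
    cc$clinical >= criteria@minClinical &
    cc$immunologic >= criteria@minImmunologic
  standalone <- rep(FALSE, ncol(fmat))
  for (s in criteria@standalone)
    standalone <- standalone | (evaluatePredicate(s, fmat) == 1L)
  data.frame(score = as.numeric(score),
             classified = as.integer(base | standalone),
             entry_failed = 0L)
}

.scoreDomainWeighted <- function(fmat, criteria) {
  P <- .predicateMatrix(criteria, fmat)
  it <- criteria@items
  W <- P * it$weight                       # satisfied item weights
  ## max weight among satisfied items within each domain
  domMax <- vapply(unique(it$domain), function(d) {
    w <- W[it$domain == d, , drop = FALSE]
    apply(w, 2L, max)
  }, numeric(ncol(fmat)))
  domMax <- matrix(domMax, nrow = ncol(fmat))
  score <- rowSums(pmax(domMax, 0))
  entryOK <- if (is.na(criteria@entry)) rep(TRUE, ncol(fmat))
             else evaluatePredicate(criteria@entry, fmat) == 1L
  cc <- .categoryCounts(criteria, P)
  classified <- entryOK & .classify(score, criteria) &
    cc$clinical >= criteria@minClinical &
    cc$immunologic >= criteria@minImmunologic
  score[!entryOK] <- 0
  data.frame(score = as.numeric(score),
             classified = as.integer(classified),
             entry_failed = as.integer(!entryOK))
}

.applyCriteriaCore <- function(fmat, criteria) {
  stopifnot(is(criteria, "CriteriaSet"))
  validObject(criteria)
  if (ncol(fmat) == 0L)
    return(data.frame(patient_id = character(0), criteria = character(0),
                      score = numeric(0), classified = integer(0),
                      entry_failed = integer(0)))
  res <- switch(criteria@ruleKind,
    weighted_sum_threshold = .scoreWeightedSum(fmat, criteria),
    count_threshold = .scoreCountThreshold(fmat, criteria),
    domain_weighted_threshold = .scoreDomainWeighted(fmat, criteria),
    stop(sprintf("unknown rule kind '%s'", criteria@ruleKind), call. = FALSE))
  ids <- colnames(fmat) %||% as.character(seq_len(ncol(fmat)))
  cbind(data.frame(patient_id = ids, criteria = criteria@name,
                   stringsAsFactors = FALSE), res)
}

#' @rdname applyCriteria
setMethod("applyCriteria", signature("SLECohort", "CriteriaSet"),
  function(cohort, criteria) .applyCriteriaCore(featureMatrix(cohort), criteria))

#' @rdname applyCriteria
setMethod("applyCriteria", signature("data.frame", "CriteriaSet"),
  function(cohort, criteria) .applyCriteriaCore(.featureMatrix(cohort), criteria))

#' @rdname applyCriteria
setMethod("applyCriteria", signature("matrix", "CriteriaSet"),
  function(cohort, criteria) .applyCriteriaCore(.featureMatrix(cohort), criteria))

#' @rdname applyCriteria
setMethod("applyCriteria", signature("numeric", "CriteriaSet"),
  function(cohort, criteria) .applyCriteriaCore(.featureMatrix(cohort), criteria))
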