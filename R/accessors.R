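#' @rdname CriteriaSet-class
setMethod("criteriaName", "CriteriaSet", function(x) x@name)
#' @rdname CriteriaSet-class
setMethod("ruleKind", "CriteriaSet", function(x) x@ruleKind)
#' @rdname CriteriaSet-class
setMethod("itemTable", "CriteriaSet", function(x) x@items)
#' @rdname CriteriaSet-class
setMethod("decisionThreshold", "CriteriaSet", function(x)
  c(threshold = x@threshold, strict = as.numeric(x@thresholdStrict)))

setMethod("show", "CriteriaSet", function(object) {
  cat(sprintf("CriteriaSet '%s' (%s)\n", object@name, object@ruleKind))
  cat(sprintf("  %d items; threshold %s %s\n", nrow(object@items),
              if (object@thresholdStrict) ">" else ">=", object@threshold))
  if (!is.na(object@entry)) cat(sprintf("  entry predicate: %s\n", object@entry))
  if (object@minClinical > 0L || object@minImmunologic > 0L)
    cat(sprintf("  requires >= %d clinical, >= %d immunologic items\n",
                object@minClinical, object@minImmunologic))
  if (length(object@standalone))
    cat(sprintf("  %d standalone rule(s)\n", length(object@standalone)))
  if (!is.null(object@probabilityTransform))
    cat("  probability transform: yes\n")
})

#' @rdname SLECohort-class
setMethod("featureMatrix", "SLECohort", function(x) assay(x, "features"))
#' @rdname SLECohort-class
setMethod("cohortGroups", "SLECohort", function(x)
  as.character(colData(x)$group))
#' @rdname SLECohort-class
setMethod("polyA", "SLECohort", function(x) as.integer(colData(x)$polyA))
#' @rdname SLECohort-class
setMethod("indexDisease", "SLECohort", function(x)
  as.character(colData(x)$index_disease))
#' @rdname SLECohort-class
setMethod("subphenotypeFlag", "SLECohort", function(x, which) {
  which <- match.arg(which, .SUBPHENOTYPES)
  as.integer(colData(x)[[which]])
})

setMethod("show", "SLECohort", function(object) {
  g <- cohortGroups(object)
  cat(sprintf("SLECohort: %d patients (%d cases, %d controls), %d features\n",
              ncol(object), sum(g == "case"), sum(g == "control"),
              nrow(object)))
  if (!is.null(metadata(object)$seed))
    cat(sprintf("  generated with seed %s\n", metadata(object)$seed))
})

#' @rdname ConfusionMatrix-class
setMethod("cmCounts", "ConfusionMatrix", function(x)
  c(tp = x@tp, fn = x@fn, fp = x@fp, tn = x@tn))

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows: truth, cols: predicted)\n")
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              byrow = TRUE,
              dimnames = list(c("positive", "negative"), c("pos", "neg")))
  print(m)
})

#' @rdname RocResult-class
setMethod("auc", "RocResult", function(x) x@auc)

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: %d operating points, AUC = %.4f",
              length(object@thresholds), object@auc))
  if (length(object@aucCI) == 2L)
    cat(sprintf(" (95%% CI %.4f-%.4f)", object@aucCI[1L], object@aucCI[2L]))
  cat("\n")
})

#' Plot an empirical ROC curve
#'
#' @param x a \linkS4class{RocResult}.
#' @param y ignored.
#' @param ... passed to \code{plot.default}.
#' @export
setMethod("plot", signature(x = "RocResult", y = "missing"),
  function(x, y, ...) {
    graphics::plot(x@fpr, x@tpr, type = "l", xlab = "1 - specificity",
                   ylab = "sensitivity",
                   main = sprintf("AUC = %.3f", x@auc), ...)
    graphics::abline(0, 1, lty = 3)
    if (!is.null(x@operatingPoint))
      graphics::points(x@operatingPoint$fpr, x@operatingPoint$tpr, pch = 19)
  })
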