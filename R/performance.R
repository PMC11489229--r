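#' Confusion matrix from predicted and true labels
#'
#' @param predicted,truth 0/1 vectors of equal, positive length.
#' @return a \linkS4class{ConfusionMatrix}.
#' @examples
#' confusionMatrix(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusionMatrix <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("'predicted' and 'truth' must have equal length", call. = FALSE)
  if (length(predicted) == 0L) stop("empty input", call. = FALSE)
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("labels must be 0/1", call. = FALSE)
  new("ConfusionMatrix",
      tp = sum(predicted == 1 & truth == 1),
      fn = sum(predicted == 0 & truth == 1),
      fp = sum(predicted == 1 & truth == 0),
      tn = sum(predicted == 0 & truth == 0))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval via beta-distribution quantiles:
#' lower = qbeta(alpha/2; x, n-x+1) (0 when x = 0),
#' upper = qbeta(1-alpha/2; x+1, n-x) (1 when x = n).
#'
#' @param successes,trials integers, 0 <= successes <= trials, trials >= 1.
#' @param conf_level confidence level in (0, 1).
#' @return named numeric \code{c(low, high)} on the proportion scale.
#' @examples
#' round(clopperPearson(415, 435), 3)  # 0.930 0.972
#' @export
clopperPearson <- function(successes, trials, conf_level = 0.95) {
  if (conf_level <= 0 || conf_level >= 1)
    stop("conf_level must lie in (0, 1)", call. = FALSE)
  if (trials < 1 || successes < 0 || successes > trials)
    stop("need 0 <= successes <= trials, trials >= 1", call. = FALSE)
  a <- 1 - conf_level
  low <- if (successes == 0) 0 else qbeta(a / 2, successes, trials - successes + 1)
  high <- if (successes == trials) 1 else
    qbeta(1 - a / 2, successes + 1, trials - successes)
  c(low = low, high = high)
}

## Wilson score interval (optional alternative)
wilsonInterval <- function(successes, trials, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- successes / trials
  den <- 1 + z^2 / trials
  ctr <- (p + z^2 / (2 * trials)) / den
  hw <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / den
  c(low = max(0, ctr - hw), high = min(1, ctr + hw))
}

#' Sensitivity, specificity and accuracy with exact confidence intervals
#'
#' @param cm a \linkS4class{ConfusionMatrix} with at least one truth-positive
#'   and one truth-negative subject.
#' @param conf_level confidence level, default 0.95.
#' @param ci_method \code{"clopper-pearson"} (exact, default) or
#'   \code{"wilson"}.
#' @return data.frame with one row per metric: \code{metric},
#'   \code{numerator}, \code{denominator}, \code{point_pct},
#'   \code{ci_low_pct}, \code{ci_high_pct}, \code{conf_level}. Percentages
#'   are unrounded; printed tables round half away from zero to one decimal
#'   (\code{\link{roundHalfAway}}).
#' @examples
#' cm <- new("ConfusionMatrix", tp = 415L, fn = 20L, fp = 31L, tn = 399L)
#' diagnosticMetrics(cm)  # sensitivity 95.4, specificity 92.8, accuracy 94.1
#' @export
diagnosticMetrics <- function(cm, conf_level = 0.95,
                              ci_method = c("clopper-pearson", "wilson")) {
  stopifnot(is(cm, "ConfusionMatrix"))
  ci_method <- match.arg(ci_method)
  P <- cm@tp + cm@fn; N <- cm@fp + cm@tn
  if (P == 0L) stop("sensitivity undefined: no truth-positive subjects",
                    call. = FALSE)
  if (N == 0L) stop("specificity undefined: no truth-negative subjects",
                    call. = FALSE)
  ciFun <- if (ci_method == "clopper-pearson") clopperPearson else wilsonInterval
  one <- function(metric, num, den) {
    ci <- ciFun(num, den, conf_level)
    data.frame(metric = metric, numerator = num, denominator = den,
               point_pct = 100 * num / den,
               ci_low_pct = 100 * ci[["low"]], ci_high_pct = 100 * ci[["high"]],
               conf_level = conf_level, stringsAsFactors = FALSE)
  }
  rbind(one("sensitivity", cm@tp, P),
        one("specificity", cm@tn, N),
        one("accuracy", cm@tp + cm@tn, P + N))
}

#' Empirical ROC curve and AUC
#'
#' Builds the empirical ROC over all distinct score thresholds (predict
#' positive when score >= threshold) and computes the AUC by the trapezoid
#' rule. Tied scores contribute half-concordance, so the AUC equals the
#' Mann-Whitney U statistic scaled by n1*n2 (midrank convention).
#'
#' @param scores finite numeric scores (higher = more case-like).
#' @param truth 0/1 vector; both classes must be present.
#' @param ci logical, compute a DeLong confidence interval for the AUC.
#' @param conf_level confidence level for the DeLong interval.
#' @param operating_threshold optional score cutoff to mark on the curve
#'   (e.g. a criteria set's decision threshold).
#' @return a \linkS4class{RocResult}.
#' @examples
#' roc <- rocCurve(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' auc(roc)  # 1
#' @export
rocCurve <- function(scores, truth, ci = FALSE, conf_level = 0.95,
                     operating_threshold = NULL) {
  if (length(scores) != length(truth))
    stop("'scores' and 'truth' must have equal length", call. = FALSE)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (!all(truth %in% c(0, 1))) stop("truth must be 0/1", call. = FALSE)
  nPos <- sum(truth == 1); nNeg <- sum(truth == 0)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present in 'truth'", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & truth == 1) / nPos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == 0) / nNeg,
                numeric(1))
  aucVal <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  op <- NULL
  if (!is.null(operating_threshold))
    op <- list(threshold = operating_threshold,
               tpr = sum(scores >= operating_threshold & truth == 1) / nPos,
               fpr = sum(scores >= operating_threshold & truth == 0) / nNeg)
  aucCI <- numeric(0)
  if (ci) aucCI <- .delongCI(scores, truth, aucVal, conf_level)
  new("RocResult", thresholds = thr, tpr = tpr, fpr = fpr, auc = aucVal,
      aucCI = aucCI, operatingPoint = op)
}

## DeLong (1988) variance of the AUC via placement values.
.delongCI <- function(scores, truth, aucVal, conf_level) {
  x <- scores[truth == 1]; y <- scores[truth == 0]
  m <- length(x); n <- length(y)
  v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n,
                numeric(1))
  v01 <- vapply(y, function(yi) (sum(x > yi) + 0.5 * sum(x == yi)) / m,
                numeric(1))
  v <- stats::var(v10) / m + stats::var(v01) / n
  z <- qnorm(1 - (1 - conf_level) / 2)
  c(low = max(0, aucVal - z * sqrt(v)), high = min(1, aucVal + z * sqrt(v)))
}

#' Subgroup (stratified) diagnostic performance
#'
#' Sensitivity is computed on the filtered subset of cases only; the full
#' control group is always retained, so specificity is identical across
#' strata; accuracy is computed on the union.
#'
#' @param cohort an \linkS4class{SLECohort}.
#' @param results classification results for this cohort from
#'   \code{\link{applyCriteria}} (order-aligned with the cohort's patients).
#' @param case_filter logical vector over all patients (only its values on
#'   cases matter), or a function of the cohort's \code{colData} data.frame
#'   returning one.
#' @param conf_level confidence level.
#' @param ci_method interval method, see \code{\link{diagnosticMetrics}}.
#' @return data.frame as from \code{\link{diagnosticMetrics}}.
#' @examples
#' coh <- generateCohort(defaultCohortSpec(), seed = 7)
#' res <- applyCriteria(coh, bundledCriteria("SLERPI"))
#' stratifiedPerformance(coh, res, function(cd) cd$nephritis == 1)
#' @export
stratifiedPerformance <- function(cohort, results, case_filter,
                                  conf_level = 0.95,
                                  ci_method = "clopper-pearson") {
  stopifnot(is(cohort, "SLECohort"))
  if (nrow(results) != ncol(cohort) ||
      !identical(results$patient_id, colnames(cohort)))
    stop("results are not aligned with the cohort's patients", call. = FALSE)
  if (is.function(case_filter))
    case_filter <- case_filter(as.data.frame(colData(cohort)))
  case_filter <- as.logical(case_filter)
  grp <- cohortGroups(cohort)
  keep <- grp == "control" | (grp == "case" & case_filter)
  if (!any(grp == "case" & case_filter))
    stop("case_filter selects no cases", call. = FALSE)
  cm <- confusionMatrix(results$classified[keep],
                        as.integer(grp[keep] == "case"))
  diagnosticMetrics(cm, conf_level, ci_method)
}

#' Reconstruct an integer count from a printed percentage
#'
#' Finds the unique integer k in [0, denominator] whose percentage
#' 100*k/denominator rounds (half away from zero, one decimal) to
#' \code{rate_pct}. Used to recover confusion-matrix cells from published
#' sensitivity/specificity tables.
#'
#' @param rate_pct percentage printed to one decimal.
#' @param denominator positive integer group size.
#' @return the unique integer count.
#' @examples
#' reconstructCount(95.4, 435)  # 415
#' @export
reconstructCount <- function(rate_pct, denominator) {
  if (denominator < 1) stop("denominator must be >= 1", call. = FALSE)
  k <- 0:denominator
  hit <- k[roundHalfAway(100 * k / denominator, 1L) == rate_pct]
  if (length(hit) == 0L)
    stop(sprintf("no count in 0..%d yields %.1f%%: inconsistent rate",
                 denominator, rate_pct), call. = FALSE)
  if (length(hit) > 1L)
    stop(sprintf("ambiguous rate: counts {%s} all yield %.1f%% of %d",
                 paste(hit, collapse = ", "), rate_pct, denominator),
         call. = FALSE)
  hit
}
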