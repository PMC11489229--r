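#' Multiple linear regression of an outcome on binary features
#'
#' Ordinary least squares (via \code{stats::lm}, i.e. a QR decomposition
#' equivalent to the normal equations) of a continuous outcome -- by default
#' the SLERPI score or probability -- on a matrix of binary clinical
#' features. Constant columns are dropped with a warning naming them (in a
#' case-control registry some features are structurally absent in one group,
#' e.g. interstitial lung disease in cases); remaining rank deficiency is an
#' error listing the collinear columns.
#'
#' @param outcome numeric vector.
#' @param design data.frame or matrix of 0/1 predictors, one column per
#'   feature.
#' @return object of class \code{"slerpRegression"}: list with
#'   \code{coefficients} (data.frame: feature, beta, se, t, p),
#'   \code{intercept}, \code{n}, \code{r_squared}, \code{dropped}.
#' @examples
#' x <- rep(0:1, each = 10)
#' fit <- olsRegression(5 + 2 * x, data.frame(x = x))
#' fit$coefficients$beta  # 2
#' @export
olsRegression <- function(outcome, design) {
  design <- as.data.frame(design)
  if (length(outcome) != nrow(design))
    stop("outcome and design have different lengths", call. = FALSE)
  keep <- complete.cases(design) & !is.na(outcome)
  outcome <- outcome[keep]; design <- design[keep, , drop = FALSE]
  const <- vapply(design, function(col) length(unique(col)) < 2L, logical(1))
  if (any(const)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(names(design)[const], collapse = ", ")),
            call. = FALSE)
    design <- design[, !const, drop = FALSE]
  }
  if (nrow(design) <= ncol(design) + 1L)
    stop("need n > number of predictors + 1", call. = FALSE)
  X <- as.matrix(design)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X) + 1L)] - 1L]
    stop(sprintf("design is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  fit <- lm(outcome ~ ., data = data.frame(outcome = outcome, design,
                                           check.names = FALSE))
  sm <- summary(fit)
  ct <- sm$coefficients
  out <- list(
    coefficients = data.frame(
      feature = rownames(ct)[-1L],
      beta = ct[-1L, "Estimate"], se = ct[-1L, "Std. Error"],
      t = ct[-1L, "t value"], p = ct[-1L, "Pr(>|t|)"],
      row.names = NULL, stringsAsFactors = FALSE),
    intercept = unname(ct[1L, "Estimate"]),
    n = length(outcome),
    r_squared = sm$r.squared,
    dropped = names(const)[const])
  class(out) <- "slerpRegression"
  out
}

#' @export
print.slerpRegression <- function(x, ...) {
  cat(sprintf("OLS regression: n = %d, R-squared = %.4f\n", x$n, x$r_squared))
  tab <- x$coefficients
  tab$p <- formatPValue(tab$p)
  tab$beta <- sprintf("%.2f", tab$beta)
  tab$se <- sprintf("%.3f", tab$se)
  tab$t <- sprintf("%.2f", tab$t)
  print(tab, row.names = FALSE)
  if (length(x$dropped))
    cat("dropped constant column(s):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

.testResult <- function(statistic, p_value, method, n1, n2 = NA_integer_,
                        extra = list()) {
  out <- c(list(statistic = unname(statistic), p_value = unname(p_value),
                method = method, n1 = n1, n2 = n2), extra)
  class(out) <- "slerpTest"
  out
}

#' @export
print.slerpTest <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %s (n1 = %d%s)\n", x$method,
              x$statistic, formatPValue(x$p_value), x$n1,
              if (is.na(x$n2)) "" else sprintf(", n2 = %d", x$n2)))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test with the midrank tie convention: U counts pairs
#' (a, b) with a > b, ties counted one half. Small untied samples use the
#' exact null distribution; otherwise a tie-corrected normal approximation
#' with continuity correction (both via \code{stats::wilcox.test}, whose W
#' statistic is exactly U for the first sample).
#'
#' @param sample_a,sample_b nonempty numeric vectors.
#' @return a \code{"slerpTest"}: U statistic for \code{sample_a}, p-value,
#'   sample sizes.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$statistic  # 0
#' @export
mannWhitneyU <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be nonempty", call. = FALSE)
  exact <- length(sample_a) < 8L && length(sample_b) < 8L &&
    !anyDuplicated(c(sample_a, sample_b))
  wt <- suppressWarnings(
    wilcox.test(sample_a, sample_b, exact = exact, correct = TRUE))
  .testResult(wt$statistic, wt$p.value, "mann_whitney",
              length(sample_a), length(sample_b))
}

#' Chi-square test of independence
#'
#' Pearson chi-square on a 2 x k contingency table with (r-1)(k-1) degrees of
#' freedom; the Yates continuity correction is applied for 2 x 2 tables
#' unless disabled.
#'
#' @param table matrix of nonnegative integer counts; all row and column
#'   totals must be positive.
#' @param correct logical, apply the Yates correction for 2 x 2 tables.
#' @return a \code{"slerpTest"} with the statistic, p-value and \code{df}.
#' @examples
#' chiSquareIndependence(matrix(c(397, 38, 366, 64), 2, byrow = TRUE))
#' @export
chiSquareIndependence <- function(table, correct = TRUE) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all marginal totals must be positive", call. = FALSE)
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  .testResult(ct$statistic, ct$p.value, "chi_square",
              sum(table[1L, ]), sum(table[-1L, ]),
              extra = list(df = unname(ct$parameter)))
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS distance against a normal with mean and SD estimated from
#' the data. Because the parameters are estimated, the plain KS p-value is
#' anti-conservative; the Lilliefors-corrected p-value
#' (\code{nortest::lillie.test}) is reported as the default, with the plain
#' KS p-value alongside.
#'
#' @param sample numeric vector; intended for n >= 50 (a warning is issued
#'   below), constant samples are an error.
#' @return a \code{"slerpTest"}: Lilliefors D statistic and p-value, with
#'   \code{p_plain_ks} for the uncorrected test.
#' @examples
#' set.seed(1)
#' ksNormality(rnorm(100))
#' @export
ksNormality <- function(sample) {
  sample <- sample[!is.na(sample)]
  if (length(unique(sample)) < 2L)
    stop("sample is constant: normality test undefined", call. = FALSE)
  if (length(sample) < 50L)
    warning("KS normality screening is intended for n >= 50", call. = FALSE)
  lt <- nortest::lillie.test(sample)
  plain <- suppressWarnings(
    ks.test(sample, "pnorm", mean(sample), sd(sample)))
  .testResult(lt$statistic, lt$p.value, "ks_normality", length(sample),
              extra = list(p_plain_ks = plain$p.value))
}
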