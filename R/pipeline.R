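#' Run the full evaluation pipeline
#'
#' Generates (or takes) a cohort, scores it under every supplied criteria
#' set, and assembles the evaluation report: per-criteria performance
#' overall, within the overt-polyautoimmunity strata and within the
#' case subphenotypes; the ordinal category distribution for criteria sets
#' that yield probabilities; an OLS regression of the SLERPI score (or
#' probability, when available) on the 14 SLERPI features; and the SLERPI
#' ROC/AUC overall and excluding polyautoimmune cases. Deterministic given
#' the seed.
#'
#' @param cohort an \linkS4class{SLECohort}, or \code{NULL} to generate one
#'   from \code{spec}.
#' @param spec a \linkS4class{CohortSpec} used when \code{cohort} is
#'   \code{NULL}; default \code{\link{defaultCohortSpec}()}.
#' @param criteria named list of \linkS4class{CriteriaSet}s (nonempty);
#'   default the four bundled sets.
#' @param strata character subset of \code{"polyA"},
#'   \code{"neuropsychiatric"}, \code{"nephritis"}, \code{"hematological"}.
#' @param conf_level confidence level in (0, 1).
#' @param seed integer seed (generation only).
#' @param out_file optional path; when given the report is written there as
#'   canonical JSON.
#' @return the report, a nested list; see the vignette for its layout.
#' @examples
#' rep <- runPipeline(seed = 7, strata = "polyA")
#' rep$performance$SLERPI$overall
#' @export
runPipeline <- function(cohort = NULL, spec = defaultCohortSpec(),
                        criteria = bundledCriteria(),
                        strata = c("polyA", "neuropsychiatric", "nephritis",
                                   "hematological"),
                        conf_level = 0.95, seed = 1L, out_file = NULL) {
  if (conf_level <= 0 || conf_level >= 1)
    stop("conf_level must lie in (0, 1)", call. = FALSE)
  if (is(criteria, "CriteriaSet")) criteria <- setNames(
    list(criteria), criteriaName(criteria))
  if (!length(criteria)) stop("'criteria' must be nonempty", call. = FALSE)
  if (is.null(names(criteria)))
    names(criteria) <- vapply(criteria, criteriaName, character(1))
  strata <- match.arg(strata, several.ok = TRUE)
  if (is.null(cohort)) cohort <- generateCohort(spec, seed = seed)
  stopifnot(is(cohort, "SLECohort"))

  grp <- cohortGroups(cohort)
  truth <- as.integer(grp == "case")
  cd <- as.data.frame(colData(cohort))

  metricsList <- function(df) {
    ## one named block per metric for stable JSON
    out <- lapply(seq_len(nrow(df)), function(i) list(
      numerator = df$numerator[i], denominator = df$denominator[i],
      point_pct = roundHalfAway(df$point_pct[i], 1L),
      ci_low_pct = roundHalfAway(df$ci_low_pct[i], 1L),
      ci_high_pct = roundHalfAway(df$ci_high_pct[i], 1L)))
    names(out) <- df$metric
    out
  }

  perf <- list(); categories <- list(); rocBlock <- list()
  for (nm in names(criteria)) {
    cs <- criteria[[nm]]
    res <- tryCatch(applyCriteria(cohort, cs), error = function(e)
      stop(sprintf("scoring stage failed for criteria '%s': %s", nm,
                   conditionMessage(e)), call. = FALSE))
    blocks <- list(overall = metricsList(diagnosticMetrics(
      confusionMatrix(res$classified, truth), conf_level)))
    for (st in strata) {
      if (st == "polyA") {
        blocks$polyA_positive <- metricsList(stratifiedPerformance(
          cohort, res, cd$polyA == 1, conf_level))
        blocks$polyA_negative <- metricsList(stratifiedPerformance(
          cohort, res, cd$polyA == 0, conf_level))
      } else {
        blocks[[st]] <- metricsList(stratifiedPerformance(
          cohort, res, cd[[st]] == 1, conf_level))
      }
    }
    perf[[nm]] <- blocks
    if ("category" %in% names(res)) {
      tab <- table(factor(res$category[truth == 1],
                          levels = c("definite", "likely", "possible",
                                     "unlikely")))
      categories[[nm]] <- list(
        counts = as.list(as.integer(tab)) |> setNames(names(tab)),
        percent = as.list(roundHalfAway(100 * as.integer(tab) / sum(tab), 1L)) |>
          setNames(names(tab)))
    }
    scoreCol <- if ("probability_pct" %in% names(res)) res$probability_pct
                else res$score
    keepNeg <- cd$polyA == 0 | truth == 0
    rocAll <- rocCurve(scoreCol, truth, ci = TRUE, conf_level = conf_level,
                       operating_threshold = cs@threshold)
    rocNoPolyA <- rocCurve(scoreCol[keepNeg], truth[keepNeg], ci = TRUE,
                           conf_level = conf_level)
    rocBlock[[nm]] <- list(
      auc = rocAll@auc, auc_ci = as.list(rocAll@aucCI),
      auc_without_polyA = rocNoPolyA@auc,
      auc_without_polyA_ci = as.list(rocNoPolyA@aucCI))
  }

  ## feature regression: SLERPI score (or probability when available) on the
  ## 14 SLERPI features, pooled over cases and controls
  regression <- NULL
  if ("SLERPI" %in% names(criteria)) {
    res <- applyCriteria(cohort, criteria$SLERPI)
    outcome <- if ("probability_pct" %in% names(res)) res$probability_pct
               else res$score
    X <- as.data.frame(t(featureMatrix(cohort)[featureVocabulary("core"), ,
                                               drop = FALSE]))
    fit <- withCallingHandlers(
      olsRegression(outcome, X),
      warning = function(w) {
        message("regression: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    regression <- list(
      outcome = if ("probability_pct" %in% names(res)) "probability_pct"
                else "score",
      n = fit$n, r_squared = fit$r_squared, intercept = fit$intercept,
      dropped = as.list(fit$dropped),
      coefficients = lapply(seq_len(nrow(fit$coefficients)), function(i)
        as.list(fit$coefficients[i, -1L])) |>
        setNames(fit$coefficients$feature))
  }

  cfg <- list(n_case = sum(truth), n_control = sum(truth == 0),
              criteria = names(criteria), strata = strata,
              conf_level = conf_level, seed = as.integer(seed))
  report <- list(
    provenance = list(package_version = as.character(packageVersion("SLEclassify")),
                      seed = as.integer(seed), config = cfg,
                      config_hash = configHash(cfg)),
    performance = perf,
    category_distribution = categories,
    roc = rocBlock,
    regression = regression)
  if (!is.null(out_file)) writeReportJson(report, out_file)
  report
}

#' Write an evaluation report as canonical JSON
#'
#' @param report a report list from \code{\link{runPipeline}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeReportJson <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       null = "null", pretty = TRUE)
  invisible(path)
}
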