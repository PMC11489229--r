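.MANDATORY_COLS <- c("id", "group", "polyA", "index_disease", .SUBPHENOTYPES)
.DEMO_COLS <- c("age_years", "age_onset_years", "age_dx_years", "sex")

#' Build an SLECohort from a patient table
#'
#' @param df data.frame, one row per patient: mandatory columns \code{id},
#'   \code{group}, \code{polyA}, \code{index_disease},
#'   \code{neuropsychiatric}, \code{nephritis}, \code{hematological}; one
#'   0/1 column per vocabulary feature (absent features are filled with 0);
#'   optional demographics (\code{age_years}, \code{age_onset_years},
#'   \code{age_dx_years}, \code{sex}).
#' @return an \linkS4class{SLECohort}.
#' @export
cohortFromDataFrame <- function(df) {
  miss <- setdiff(.MANDATORY_COLS, names(df))
  if (length(miss))
    stop(sprintf("cohort table lacks mandatory column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  feats <- intersect(featureVocabulary(), names(df))
  for (f in feats) {
    bad <- which(!df[[f]] %in% c(0, 1))
    if (length(bad))
      stop(sprintf("feature '%s' has non-binary value in row %d", f, bad[1L]),
           call. = FALSE)
  }
  extra <- setdiff(names(df), c(.MANDATORY_COLS, .DEMO_COLS,
                                featureVocabulary()))
  if (length(extra))
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  m <- matrix(0L, length(featureVocabulary()), nrow(df),
              dimnames = list(featureVocabulary(), df$id))
  for (f in feats) m[f, ] <- as.integer(df[[f]])
  cd <- DataFrame(
    group = as.character(df$group),
    polyA = as.integer(df$polyA),
    index_disease = as.character(df$index_disease),
    neuropsychiatric = as.integer(df$neuropsychiatric),
    nephritis = as.integer(df$nephritis),
    hematological = as.integer(df$hematological),
    row.names = df$id)
  for (col in .DEMO_COLS) if (col %in% names(df)) cd[[col]] <- df[[col]]
  out <- new("SLECohort",
             SummarizedExperiment(assays = list(features = m), colData = cd))
  validObject(out)
  out
}

#' Convert an SLECohort to a patient table
#'
#' Inverse of \code{\link{cohortFromDataFrame}}: one row per patient,
#' metadata columns first, then one 0/1 column per vocabulary feature.
#'
#' @param cohort an \linkS4class{SLECohort}.
#' @return data.frame.
#' @export
cohortToDataFrame <- function(cohort) {
  stopifnot(is(cohort, "SLECohort"))
  cd <- as.data.frame(colData(cohort))
  df <- cbind(data.frame(id = colnames(cohort), stringsAsFactors = FALSE),
              cd, as.data.frame(t(featureMatrix(cohort))))
  rownames(df) <- NULL
  df
}

#' Read / write a cohort CSV
#'
#' The cohort CSV has one row per patient with a header: mandatory columns
#' \code{id}, \code{group}, \code{polyA}, \code{index_disease}, the three
#' subphenotype flags, then one 0/1 column per feature. Unknown columns are
#' preserved-with-warning on read (ignored in the returned object); a missing
#' mandatory column or a non-binary feature value is an error naming the
#' column (and row).
#'
#' @param path file path.
#' @return \code{readCohortCsv} returns an \linkS4class{SLECohort};
#'   \code{writeCohortCsv} returns \code{path} invisibly.
#' @examples
#' coh <- generateCohort(defaultCohortSpec(), seed = 7)
#' f <- tempfile(fileext = ".csv")
#' writeCohortCsv(coh, f)
#' coh2 <- readCohortCsv(f)
#' @export
readCohortCsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  cohortFromDataFrame(df)
}

#' @rdname readCohortCsv
#' @param cohort an \linkS4class{SLECohort}.
#' @export
writeCohortCsv <- function(cohort, path) {
  write.csv(cohortToDataFrame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
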