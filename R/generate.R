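## Synthetic case-control cohort generation.

## Marginal-preserving correlated binary draws: latent Gaussian copula.
## Z ~ N(0, R); X_f = 1{Z_f < qnorm(p_f)} has P(X_f = 1) = p_f exactly.
.drawFeatures <- function(n, prev, correlation = NULL) {
  feats <- names(prev)
  if (is.null(correlation)) {
    m <- matrix(rbinom(length(feats) * n, 1L, rep(prev, times = n)),
                nrow = length(feats), dimnames = list(feats, NULL))
    return(m)
  }
  R <- correlation[feats, feats]
  ee <- eigen(R, symmetric = TRUE)            # PSD-safe square root
  L <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), nrow(R))
  Z <- L %*% matrix(rnorm(nrow(R) * n), nrow(R), n)
  m <- (Z < qnorm(prev)) * 1L
  storage.mode(m) <- "integer"
  rownames(m) <- feats
  m
}

## log-normal matched to a printed median and IQR (demographics only)
.rlnormMatched <- function(n, med, q1, q3) {
  rlnorm(n, meanlog = log(med), sdlog = log(q3 / q1) / (2 * qnorm(0.75)))
}

#' Generate a synthetic case-control cohort
#'
#' Draws one cohort from a \linkS4class{CohortSpec}: per-feature Bernoulli
#' draws at the group prevalences (independent by default; a latent
#' Gaussian-copula scheme preserving the marginals when \code{correlation}
#' is supplied), overt-polyautoimmunity flags, the control index-disease
#' mix, subphenotype flags and cosmetic demographics. Fully reproducible
#' from the seed.
#'
#' Under the default \code{"feature_coupled"} subphenotype rule the flags are
#' derived from the features themselves -- neuropsychiatric from the
#' neurological-disorder feature, nephritis from proteinuria (so nephritis
#' implies proteinuria), hematological from leucopenia OR
#' thrombocytopenia/AIHA OR anemia -- mirroring the near-identical printed
#' counts. Under \code{"independent"} the flags are drawn at the printed case
#' frequencies (88/435, 125/435, 173/435) unlinked to the features.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param seed integer; defaults to the spec's seed.
#' @return an \linkS4class{SLECohort}; \code{metadata()} carries the spec and
#'   the seed used.
#' @examples
#' coh <- generateCohort(defaultCohortSpec(), seed = 7)
#' coh
#' @export
generateCohort <- function(spec, seed = spec@seed) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  set.seed(as.integer(seed))
  nCa <- spec@nCase; nCo <- spec@nControl
  mCase <- .drawFeatures(nCa, spec@prevalence$case, spec@correlation)
  mCtrl <- .drawFeatures(nCo, spec@prevalence$control, spec@correlation)
  colnames(mCase) <- sprintf("case_%04d", seq_len(nCa))
  colnames(mCtrl) <- sprintf("ctrl_%04d", seq_len(nCo))
  m <- cbind(mCase, mCtrl)

  group <- c(rep("case", nCa), rep("control", nCo))
  polyA <- c(rbinom(nCa, 1L, spec@polyAFreq[["case"]]),
             rbinom(nCo, 1L, spec@polyAFreq[["control"]]))
  indexDis <- c(rep("SLE", nCa),
                sample(rep(names(spec@controlMix), times = spec@controlMix)))

  sub <- matrix(0L, nCa + nCo, 3L,
                dimnames = list(NULL, .SUBPHENOTYPES))
  ca <- seq_len(nCa)
  if (spec@subphenotypeRule == "feature_coupled") {
    sub[ca, "neuropsychiatric"] <- m["neurological_disorder", ca]
    sub[ca, "nephritis"] <- m["proteinuria", ca]
    sub[ca, "hematological"] <- evaluatePredicate(
      "or(leucopenia, thrombocytopenia_aiha, anemia)", m[, ca, drop = FALSE])
  } else {
    sub[ca, "neuropsychiatric"] <- rbinom(nCa, 1L, 88 / 435)
    sub[ca, "nephritis"] <- rbinom(nCa, 1L, 125 / 435)
    sub[ca, "hematological"] <- rbinom(nCa, 1L, 173 / 435)
  }

  age <- c(.rlnormMatched(nCa, 48, 37, 59), .rlnormMatched(nCo, 64, 54, 70.5))
  ageOn <- c(.rlnormMatched(nCa, 26.5, 19, 36), .rlnormMatched(nCo, 40, 29, 50))
  ageDx <- c(.rlnormMatched(nCa, 28.5, 22, 40), .rlnormMatched(nCo, 44, 33.5, 53))
  sex <- ifelse(c(rbinom(nCa, 1L, 0.913), rbinom(nCo, 1L, 0.851)) == 1L,
                "F", "M")

  cd <- DataFrame(
    group = group, polyA = polyA, index_disease = indexDis,
    neuropsychiatric = sub[, "neuropsychiatric"],
    nephritis = sub[, "nephritis"],
    hematological = sub[, "hematological"],
    age_years = age, age_onset_years = ageOn, age_dx_years = ageDx,
    sex = sex, row.names = colnames(m))

  se <- SummarizedExperiment(assays = list(features = m), colData = cd)
  out <- new("SLECohort", se)
  metadata(out)$spec <- spec
  metadata(out)$seed <- as.integer(seed)
  validObject(out)
  out
}

#' Empirical feature prevalence in one group
#'
#' @param cohort an \linkS4class{SLECohort}.
#' @param feature vocabulary feature name.
#' @param group \code{"case"} or \code{"control"}.
#' @return named numeric: \code{count}, \code{n} and \code{prevalence}
#'   (count / group size).
#' @examples
#' coh <- generateCohort(defaultCohortSpec(), seed = 7)
#' empiricalPrevalence(coh, "ana", "case")
#' @export
empiricalPrevalence <- function(cohort, feature, group = c("case", "control")) {
  stopifnot(is(cohort, "SLECohort"))
  group <- match.arg(group)
  if (!feature %in% featureVocabulary())
    stop(sprintf("'%s' is not a declared feature", feature), call. = FALSE)
  sel <- cohortGroups(cohort) == group
  if (!any(sel)) stop(sprintf("no patients in group '%s'", group),
                      call. = FALSE)
  v <- featureMatrix(cohort)[feature, sel]
  c(count = sum(v), n = length(v), prevalence = mean(v))
}
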