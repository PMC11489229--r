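#' Construct a CohortSpec
#'
#' @param nCase,nControl group sizes.
#' @param prevalence list with named numeric vectors \code{case} and
#'   \code{control} of per-feature Bernoulli prevalences. Vocabulary features
#'   absent from a vector default to prevalence 0.
#' @param polyAFreq named numeric \code{c(case=, control=)}:
#'   overt-polyautoimmunity frequency per group.
#' @param controlMix named counts of control index diseases (must sum to
#'   \code{nControl}) or proportions summing to 1.
#' @param subphenotypeRule \code{"feature_coupled"} or \code{"independent"}.
#' @param correlation optional latent Gaussian-copula correlation matrix over
#'   \code{names(prevalence$case)} (unit diagonal, PSD), or \code{NULL}.
#' @param seed integer default generator seed.
#' @return a validated \linkS4class{CohortSpec}.
#' @seealso \code{\link{defaultCohortSpec}}, \code{\link{generateCohort}}
#' @export
cohortSpec <- function(nCase, nControl, prevalence, polyAFreq = c(case = 0, control = 0),
                       controlMix = c(RA = 1), subphenotypeRule = "feature_coupled",
                       correlation = NULL, seed = 1L) {
  nControl <- as.integer(nControl)
  if (!isTRUE(all.equal(sum(controlMix), nControl)) && sum(controlMix) <= 1 + 1e-9) {
    ## proportions: convert to counts, largest-remainder apportionment
    raw <- controlMix * nControl
    cnt <- floor(raw)
    rem <- nControl - sum(cnt)
    if (rem > 0) {
      o <- order(raw - cnt, decreasing = TRUE)
      cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
    }
    controlMix <- cnt
  }
  for (g in c("case", "control")) {
    p <- prevalence[[g]] %||% numeric(0)
    missing <- setdiff(featureVocabulary(), names(p))
    prevalence[[g]] <- c(p, setNames(rep(0, length(missing)), missing))
    prevalence[[g]] <- prevalence[[g]][featureVocabulary()]
  }
  if (!is.null(correlation)) {
    ## align/order to the full vocabulary, identity elsewhere
    feats <- featureVocabulary()
    R <- diag(length(feats)); dimnames(R) <- list(feats, feats)
    R[rownames(correlation), colnames(correlation)] <- correlation
    correlation <- R
  }
  new("CohortSpec", nCase = as.integer(nCase), nControl = nControl,
      prevalence = prevalence, polyAFreq = polyAFreq,
      controlMix = setNames(as.integer(round(controlMix)), names(controlMix)),
      subphenotypeRule = subphenotypeRule, correlation = correlation,
      seed = as.integer(seed))
}

#' Default cohort specification: the published registry structure
#'
#' Returns the generator parameterisation emulating the published Colombian
#' case-control registry: 435 SLE cases and 430 autoimmune-disease controls;
#' per-group prevalences of the 14 SLERPI features taken from the printed
#' descriptive table; overt polyautoimmunity at 18.4 percent in both groups;
#' and the control index-disease mix (RA 253, Sjogren 56, autoimmune thyroid
#' disease 43, multiple sclerosis 47, systemic sclerosis 30, antiphospholipid
#' syndrome 1). Auxiliary features (anemia, biopsy-proven nephritis, granular
#' autoantibodies, photosensitivity, fever) are not described in the printed
#' table and default to prevalence 0; override through \code{prevalence}.
#'
#' @param ... overrides passed to \code{\link{cohortSpec}} (e.g.
#'   \code{correlation}, \code{subphenotypeRule}, \code{seed}).
#' @return a \linkS4class{CohortSpec}.
#' @examples
#' spec <- defaultCohortSpec()
#' spec@prevalence$case[["ana"]]  # 0.933
#' @export
defaultCohortSpec <- function(...) {
  casePrev <- c(
    malar_rash = 0.480, scle_dle = 0.147, alopecia = 0.526,
    mucosal_ulcers = 0.391, arthritis = 0.747, serositis = 0.331,
    neurological_disorder = 0.202, leucopenia = 0.402,
    thrombocytopenia_aiha = 0.103, proteinuria = 0.285, ana = 0.933,
    low_c3_c4 = 0.389, immunologic_disorder = 0.871, ild = 0.0)
  controlPrev <- c(
    malar_rash = 0.002, scle_dle = 0.0, alopecia = 0.030,
    mucosal_ulcers = 0.002, arthritis = 0.674, serositis = 0.0,
    neurological_disorder = 0.033, leucopenia = 0.074,
    thrombocytopenia_aiha = 0.014, proteinuria = 0.005, ana = 0.588,
    low_c3_c4 = 0.016, immunologic_disorder = 0.123, ild = 0.005)
  args <- list(...)
  defaults <- list(
    nCase = 435L, nControl = 430L,
    prevalence = list(case = casePrev, control = controlPrev),
    polyAFreq = c(case = 0.184, control = 0.184),
    controlMix = c(RA = 253L, SS = 56L, AITD = 43L, MS = 47L, SSc = 30L,
                   APS = 1L))
  do.call(cohortSpec, modifyList(defaults, args))
}
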