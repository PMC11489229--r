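## The declared feature vocabulary. Core block: the 14 SLERPI features, in the
## order of the registry's descriptive table. Auxiliary block: features needed
## by the comparator criteria sets or the subphenotype definitions but not part
## of the SLERPI score.

.CORE_FEATURES <- c(
  "malar_rash",            # malar or maculopapular rash
  "scle_dle",              # subacute cutaneous / discoid lupus
  "alopecia",
  "mucosal_ulcers",
  "arthritis",
  "serositis",
  "neurological_disorder",
  "leucopenia",
  "thrombocytopenia_aiha", # thrombocytopenia or autoimmune hemolytic anemia
  "proteinuria",
  "ana",                   # anti-nuclear antibodies
  "low_c3_c4",             # both C3 and C4 low
  "immunologic_disorder",  # anti-dsDNA, anti-Sm or antiphospholipid positivity
  "ild"                    # interstitial lung disease
)

.AUX_FEATURES <- c(
  "anemia",
  "biopsy_proven_nephritis",
  "anti_dsdna",
  "anti_sm",
  "antiphospholipid",
  "coombs",
  "photosensitivity",
  "fever"
)

#' Declared feature vocabulary
#'
#' Every predicate in a criteria definition, and every feature column of a
#' cohort, must use names from this vocabulary. The core block is the
#' 14-feature SLERPI panel; the auxiliary block holds items required by the
#' comparator criteria sets (e.g. biopsy-proven nephritis for the SLICC
#' standalone rule) or by the hematological-subphenotype definition (anemia).
#'
#' @param which one of \code{"all"}, \code{"core"} (the 14 SLERPI features) or
#'   \code{"aux"}.
#' @return character vector of feature names.
#' @examples
#' featureVocabulary("core")
#' @export
featureVocabulary <- function(which = c("all", "core", "aux")) {
  which <- match.arg(which)
  switch(which,
    all  = c(.CORE_FEATURES, .AUX_FEATURES),
    core = .CORE_FEATURES,
    aux  = .AUX_FEATURES
  )
}

.SUBPHENOTYPES <- c("neuropsychiatric", "nephritis", "hematological")
.INDEX_DISEASES <- c("SLE", "RA", "SS", "AITD", "MS", "SSc", "APS")
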