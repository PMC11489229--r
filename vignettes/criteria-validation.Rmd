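---
title: "Validating SLE classification criteria with SLEclassify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating SLE classification criteria with SLEclassify}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SLEclassify)
```

## The problem

Systemic lupus erythematosus (SLE) has no single diagnostic test; patients
are identified through rule-based classification criteria combining clinical
manifestations and serology. Successive criteria systems trade sensitivity
against specificity differently: ACR-1997 counts items (at least 4 of 11),
SLICC-2012 counts items under clinical/immunologic balance constraints with
an organ-dominant standalone rule for biopsy-proven nephritis, EULAR/ACR-2019
gates on ANA positivity and sums domain weights (classify at 10 or more,
counting only the highest-weighted satisfied item per domain), and the SLE
Risk Probability Index (SLERPI) is a machine-learning-derived 14-feature
weighted score whose simplified rule classifies SLE when the score strictly
exceeds 7 out of a maximum of 30.5.

`SLEclassify` implements all four systems as *data*, not code: each criteria
set is a declarative YAML file (items, boolean predicates over a shared
feature vocabulary, weights, domains, thresholds) interpreted by one engine.
Around the engine sit a synthetic case-control cohort generator and a
diagnostic-performance layer, so that a full criteria-validation study —
confusion matrices, exact confidence intervals, ROC/AUC, subgroup analyses,
feature regression — runs end to end on data with a known ground truth.

## The criteria engine

A patient record is a 0/1 vector over a declared vocabulary: the 14 SLERPI
features (malar/maculopapular rash, SCLE/DLE, alopecia, mucosal ulcers,
arthritis, serositis, neurological disorder, leucopenia,
thrombocytopenia/AIHA, proteinuria, ANA, low C3 and C4, immunologic
disorder, interstitial lung disease) plus auxiliary items the comparator
sets need (anemia, biopsy-proven nephritis, granular autoantibodies,
photosensitivity, fever). A feature missing from a record is treated as
absent (0) — the convention of retrospective registries, where unobserved
means unrecorded; this is a documented, overridable decision, not a
statistical imputation.

Three rule kinds are supported:

* **Weighted sum** (SLERPI): score $= \sum_i w_i \, x_i$; classify when the
  score exceeds the threshold (strictly, for SLERPI: a score of exactly 7
  does *not* classify). An optional logistic transform maps item indicators
  to a probability $100 \cdot \mathrm{logit}^{-1}(\beta_0 + \sum \beta_i x_i)$
  with ordinal categories.
* **Count threshold** (ACR-1997, SLICC-2012): score = number of satisfied
  items; classification additionally requires minimum counts of clinical and
  immunologic items (SLICC) or is granted outright by a standalone rule
  (SLICC: biopsy-proven nephritis with ANA or anti-dsDNA).
* **Domain-weighted** (EULAR/ACR-2019): an entry predicate (ANA) gates
  everything; per domain only the maximum weight among satisfied items
  contributes; classify at score $\ge 10$ with at least one clinical item.

```{r engine}
slerpi <- bundledCriteria("SLERPI")
slerpi
applyCriteria(c(ana = 1, immunologic_disorder = 1), slerpi)
```

### Transcription of the bundled definitions

The bundled YAML files transcribe the four published criteria systems onto
the package's feature vocabulary. The SLERPI definition is pinned by its
published anchors — threshold 7 (strict), positive weights summing to 30.5,
thrombocytopenia/AIHA at 4.5, interstitial lung disease as the single
negative weight (−1) — and the loader *enforces* the 30.5 and −1 anchors, so
an edited definition that breaks them is rejected. Because the registry
records some manifestations only at a coarse grain, a few comparator items
are condensed mappings, stated in the YAML comments: the single serositis
feature carries the EULAR/ACR effusion weight (5); the single neurological
feature carries that domain's maximum weight (5); the merged
thrombocytopenia/AIHA feature carries the shared weight 4; the composite
immunologic-disorder feature (anti-dsDNA/anti-Sm/antiphospholipid) feeds the
SLE-specific-antibody domain and the SLICC anti-dsDNA item via OR with the
granular auxiliary features. These choices are reviewable config, not code,
and every anchor the validation arithmetic depends on is asserted in the
test suite. The full-model SLERPI logistic coefficients are not bundled (the
engine supports `probability_transform` and it is exercised with toy
definitions in the tests); without it the SLERPI output is the raw score and
the binary rule, and ordinal categories are produced only for
probability-bearing definitions.

Ordinal probability categories use the published ranges — unlikely 0–14%,
possible 15–43%, likely 44–86%, definite 87–100% — implemented as the
half-open partition $[0,15), [15,44), [44,87), [87,100]$ so every percentage
maps to exactly one category (the printed integer ranges leave fractional
gaps). The EULAR/ACR "not better explained by another disease" attribution
clause is not computable from a feature table and is omitted.

## The synthetic cohort generator

Real registry data are not redistributable, so validation runs on synthetic
cohorts whose *default parameters are fixed at the published registry
structure*: 435 SLE cases and 430 autoimmune-disease controls (rheumatoid
arthritis 253, Sjögren's 56, autoimmune thyroid disease 43, multiple
sclerosis 47, systemic sclerosis 30, antiphospholipid syndrome 1); the 14
per-group feature prevalences of the published descriptive table (e.g. ANA
93.3% in cases, 58.8% in controls; interstitial lung disease 0% in cases,
0.5% in controls); overt polyautoimmunity at 18.4% in both groups.

```{r generator}
spec <- defaultCohortSpec()
cohort <- generateCohort(spec, seed = 7)
cohort
empiricalPrevalence(cohort, "ana", "case")
```

Design choices, made once:

* **Features are independent Bernoulli draws by default.** The published
  table constrains only marginals; pretending to know the joint distribution
  would be dishonest. A latent Gaussian-copula option (`correlation=`)
  exists to probe how performance metrics respond to dependence: draws
  $Z \sim N(0, R)$ thresholded at $\Phi^{-1}(p_f)$ preserve every marginal
  exactly while inducing the requested pairwise latent correlation.
* **Subphenotype flags are feature-coupled by default**: neuropsychiatric
  from the neurological-disorder feature, nephritis from proteinuria (so
  nephritis implies proteinuria), hematological from leucopenia OR
  thrombocytopenia/AIHA OR anemia — mirroring the near-identical printed
  counts (88 neuropsychiatric vs 88 with the feature, 125 nephritis vs 124
  proteinuria, 173 hematological vs 175 with a cytopenia). An
  `"independent"` mode draws the flags at the printed frequencies unlinked
  to features.
* **Auxiliary features default to prevalence 0** (they are absent from the
  published table); anemia in particular can be overridden when the
  hematological definition should have an independent contribution.
* **Ages are log-normal matched to the printed medians and IQRs**, sex
  Bernoulli at the printed proportions; demographics are cosmetic and carry
  no weight in any engine or acceptance check.
* **One global seed** drives all draws in a fixed order, so a spec plus a
  seed reproduces a cohort exactly.

What passing tests on such cohorts do and do not show: marginal structure,
group sizes, strata and the entire analysis machinery are exercised
faithfully, but the joint feature distribution of real patients (comorbidity
of rashes and serology, nephritis clustering) is *not* emulated under
independence, so synthetic sensitivity/specificity are qualitative echoes,
not estimates, of the published ones. This is why the package's acceptance
checks of the published tables rest on exact arithmetic reconstruction
(below), never on simulation.

## The performance layer

`confusionMatrix` / `diagnosticMetrics` compute sensitivity, specificity and
accuracy with exact (Clopper–Pearson) 95% intervals from beta quantiles —
the convention of the epidemiology tooling the published analysis used;
Wilson intervals are available behind a flag. Reported percentages round
half away from zero to one decimal, matching the printed tables.
`rocCurve` builds the empirical ROC over all distinct score cutoffs; its
trapezoid AUC equals the Mann–Whitney $U/(n_1 n_2)$ under the midrank tie
convention (a property test checks this against an $O(n^2)$ pair-count
oracle and against pROC). `stratifiedPerformance` filters *cases only* and
always retains the full control group — which is why specificity is
identical across subphenotype rows in the published table, an invariance the
suite asserts.

`reconstructCount` inverts a printed one-decimal percentage to the unique
integer numerator it implies (erroring on ambiguity), which lets the
published performance tables be checked for internal consistency without
any patient data: reconstruct TP and TN from the printed
sensitivity/specificity and group sizes, recompute accuracy, compare to the
printed value. Every published row passes this check except the
without-polyautoimmunity SLERPI row, whose implied accuracy rounds to 94.1
against a printed 94.2 — a printed-rounding inconsistency documented in the
test suite and excluded from the check.

```{r perf}
cm <- confusionMatrix(
  applyCriteria(cohort, slerpi)$classified,
  as.integer(cohortGroups(cohort) == "case"))
diagnosticMetrics(cm)[, c("metric", "point_pct", "ci_low_pct", "ci_high_pct")]
```

## Association statistics

`olsRegression` regresses a continuous outcome — by default the SLERPI score
itself; the probability percentage when a transform is present — on the 14
binary features, dropping structurally constant columns with a warning
(interstitial lung disease is constant-zero in cases at the default
prevalences) and erroring informatively on residual collinearity. On
synthetic cohorts the score is an exact linear function of the features, so
the fit recovers the item weights with $R^2 = 1$ — a strong end-to-end check
of engine and regression together. `mannWhitneyU` (midrank ties, exact for
small untied samples, tie-corrected normal approximation otherwise),
`chiSquareIndependence` (Yates-corrected for 2×2, disable with
`correct = FALSE`) and `ksNormality` cover the bivariate screening used in
cohort descriptions. Because the KS test here estimates mean and SD from the
sample, the plain KS p-value is anti-conservative; the Lilliefors-corrected
p-value is the default and both are reported. P-values below $10^{-4}$ print
as "<0.0001". No multiple-testing adjustment is applied, and reports say so.

## The pipeline

`runPipeline` ties the stages together: generate (or accept) a cohort, score
it under every criteria set, evaluate overall, by polyautoimmunity stratum
and by subphenotype, regress, and assemble a JSON-serialisable report with
provenance (seed, config hash, package version). Identical seed and config
give byte-identical reports.

```{r pipeline}
rep <- runPipeline(cohort = cohort, strata = "polyA", seed = 7)
str(rep$performance$SLERPI$overall)
rep$roc$SLERPI$auc
```

## Numerical choices and problem sizes

* Strict vs non-strict thresholds: SLERPI classifies on score > 7; all
  comparator thresholds are non-strict (≥). Boundary behaviour is tested
  explicitly (a SLERPI score of exactly 7 never classifies).
* Exact interval boundaries: the lower bound is 0 at zero successes and the
  upper bound 1 at full successes, by convention rather than quantile
  evaluation.
* Degenerate prevalences (0 or 1) produce constant feature columns without
  numerical failure; the copula square root uses an eigendecomposition with
  negative eigenvalues clipped at 0, so merely positive-*semi*definite
  correlation matrices are valid.
* The test suite sizes its simulations to run comfortably on one CPU: the
  marginal-recovery check generates 25,000 patients per group (every
  tabulated prevalence within 3 binomial standard errors), interval coverage
  uses 2,000 replicates at n = 435, the AUC ≡ Mann–Whitney property runs on
  1,000 random small instances, and copula-vs-independent equivalence uses
  5,000 draws per arm with per-feature chi-square tests at α = 0.01.

## Known limitations

* Synthetic cohorts carry no feature dependence by default (see above); the
  copula option is a sensitivity probe, not an estimate of the real joint
  distribution.
* The bundled SLERPI definition pins every anchor the published validation
  arithmetic states, but individual item weights beyond those anchors are
  transcriptions onto a coarse registry vocabulary; studies needing
  item-level fidelity should review (and can simply edit) the YAML.
* No missing-data mechanism and no longitudinal disease course are
  simulated; latent autoimmunity is out of scope.
* The ordinal category distribution and probability medians of the full
  SLERPI logistic model require its coefficients, which are not bundled.
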