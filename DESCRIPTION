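Package: SLEclassify
Title: Rule-Based Classification Criteria Engines and Diagnostic
    Performance Evaluation for Systemic Lupus Erythematosus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Declarative scoring engines for four systemic lupus
    erythematosus (SLE) classification criteria sets (the SLE Risk
    Probability Index simplified score, ACR-1997, SLICC-2012 and
    EULAR/ACR-2019), a reproducible synthetic case-control cohort
    generator with marginal prevalences matched to a published
    autoimmune-disease registry, and a diagnostic-performance layer:
    confusion matrices, sensitivity/specificity/accuracy with exact
    binomial confidence intervals, empirical ROC curves with
    Mann-Whitney-consistent AUC, polyautoimmunity- and
    subphenotype-stratified analyses, and feature regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    nortest
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'SLEclassify-package.R'
    'utils.R'
    'vocabulary.R'
    'predicates.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'criteria-io.R'
    'scoring.R'
    'cohort-spec.R'
    'generate.R'
    'cohort-io.R'
    'performance.R'
    'association.R'
    'pipeline.R'
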