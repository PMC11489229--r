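# SLE Risk Probability Index -- simplified score.
# Weighted sum over 14 clinical/serological features; classify as SLE when
# the score strictly exceeds 7. The 13 positive weights sum to 30.5 (the
# maximum attainable score); interstitial lung disease is the single
# negatively weighted feature (-1), counting against SLE.
# The full-model logistic probability transform is not bundled; see the
# package vignette for the transcription notes.
name: SLERPI
rule_kind: weighted_sum_threshold
threshold: 7
threshold_is_strict: true
items:
  - {item_id: malar_rash,            predicate: malar_rash,            weight: 4,   category: clinical}
  - {item_id: scle_dle,              predicate: scle_dle,              weight: 2.5, category: clinical}
  - {item_id: alopecia,              predicate: alopecia,              weight: 1.5, category: clinical}
  - {item_id: mucosal_ulcers,        predicate: mucosal_ulcers,        weight: 1,   category: clinical}
  - {item_id: arthritis,             predicate: arthritis,             weight: 1.5, category: clinical}
  - {item_id: serositis,             predicate: serositis,             weight: 1.5, category: clinical}
  - {item_id: neurological_disorder, predicate: neurological_disorder, weight: 2,   category: clinical}
  - {item_id: leucopenia,            predicate: leucopenia,            weight: 1,   category: clinical}
  - {item_id: thrombocytopenia_aiha, predicate: thrombocytopenia_aiha, weight: 4.5, category: clinical}
  - {item_id: proteinuria,           predicate: proteinuria,           weight: 2.5, category: clinical}
  - {item_id: ana,                   predicate: ana,                   weight: 3,   category: immunologic}
  - {item_id: low_c3_c4,             predicate: low_c3_c4,             weight: 1,   category: immunologic}
  - {item_id: immunologic_disorder,  predicate: immunologic_disorder,  weight: 4.5, category: immunologic}
  - {item_id: ild,                   predicate: ild,                   weight: -1,  category: clinical}
category_cutpoints: [15, 44, 87]
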