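# ACR-1997 revised classification criteria for SLE: 11 items, classify when
# at least 4 are satisfied. Items are mapped onto the registry's feature
# vocabulary (e.g. the hematologic-disorder item is leucopenia OR
# thrombocytopenia/AIHA OR anemia; the renal item is proteinuria OR
# biopsy-proven nephritis).
name: ACR-1997
rule_kind: count_threshold
threshold: 4
threshold_is_strict: false
items:
  - {item_id: malar_rash,           predicate: malar_rash,            category: clinical}
  - {item_id: discoid_rash,         predicate: scle_dle,              category: clinical}
  - {item_id: photosensitivity,     predicate: photosensitivity,      category: clinical}
  - {item_id: oral_ulcers,          predicate: mucosal_ulcers,        category: clinical}
  - {item_id: arthritis,            predicate: arthritis,             category: clinical}
  - {item_id: serositis,            predicate: serositis,             category: clinical}
  - {item_id: renal_disorder,       predicate: "or(proteinuria, biopsy_proven_nephritis)", category: clinical}
  - {item_id: neurologic_disorder,  predicate: neurological_disorder, category: clinical}
  - {item_id: hematologic_disorder, predicate: "or(leucopenia, thrombocytopenia_aiha, anemia)", category: clinical}
  - {item_id: immunologic_disorder, predicate: "or(immunologic_disorder, anti_dsdna, anti_sm, antiphospholipid)", category: immunologic}
  - {item_id: ana,                  predicate: ana,                   category: immunologic}
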