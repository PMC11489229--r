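# SLICC-2012 classification criteria for SLE: 17 items (11 clinical, 6
# immunologic); classify when >= 4 items are satisfied including at least one
# clinical and one immunologic item, OR by the standalone organ-dominant
# rule: biopsy-proven lupus nephritis with ANA or anti-dsDNA positivity.
# Condensed transcription notes: the registry records a single merged
# thrombocytopenia/AIHA feature (used for the thrombocytopenia item; the
# hemolytic-anemia item uses the anemia feature) and a composite
# immunologic-disorder feature, accepted by the anti-dsDNA item via OR.
name: SLICC-2012
rule_kind: count_threshold
threshold: 4
threshold_is_strict: false
min_clinical: 1
min_immunologic: 1
standalone:
  - "and(biopsy_proven_nephritis, or(ana, anti_dsdna))"
items:
  - {item_id: acute_cutaneous,     predicate: malar_rash,            category: clinical}
  - {item_id: chronic_cutaneous,   predicate: scle_dle,              category: clinical}
  - {item_id: oral_ulcers,         predicate: mucosal_ulcers,        category: clinical}
  - {item_id: alopecia,            predicate: alopecia,              category: clinical}
  - {item_id: synovitis,           predicate: arthritis,             category: clinical}
  - {item_id: serositis,           predicate: serositis,             category: clinical}
  - {item_id: renal,               predicate: "or(proteinuria, biopsy_proven_nephritis)", category: clinical}
  - {item_id: neurologic,          predicate: neurological_disorder, category: clinical}
  - {item_id: hemolytic_anemia,    predicate: anemia,                category: clinical}
  - {item_id: leukopenia,          predicate: leucopenia,            category: clinical}
  - {item_id: thrombocytopenia,    predicate: thrombocytopenia_aiha, category: clinical}
  - {item_id: ana,                 predicate: ana,                   category: immunologic}
  - {item_id: anti_dsdna,          predicate: "or(anti_dsdna, immunologic_disorder)", category: immunologic}
  - {item_id: anti_sm,             predicate: anti_sm,               category: immunologic}
  - {item_id: antiphospholipid,    predicate: antiphospholipid,      category: immunologic}
  - {item_id: low_complement,      predicate: low_c3_c4,             category: immunologic}
  - {item_id: direct_coombs,       predicate: coombs,                category: immunologic}
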