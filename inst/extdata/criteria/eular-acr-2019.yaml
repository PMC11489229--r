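# EULAR/ACR-2019 classification criteria for SLE. Entry criterion: ANA
# positivity; without it a patient is not classified regardless of other
# features. Additive weighted criteria grouped into domains; within each
# domain only the highest-weighted satisfied item contributes. Classify when
# the total reaches 10 with at least one clinical criterion satisfied.
# Condensed transcription onto the registry vocabulary: serositis is carried
# at the effusion weight (5); the neuropsychiatric domain is carried at its
# maximum weight (seizure, 5) from the single neurological-disorder feature;
# the merged thrombocytopenia/AIHA feature carries the shared weight 4;
# biopsy-proven nephritis is carried at the class III/IV weight (10); the
# composite immunologic-disorder feature feeds the SLE-specific-antibody
# domain (weight 6) via OR.
name: EULAR-ACR-2019
rule_kind: domain_weighted_threshold
threshold: 10
threshold_is_strict: false
entry: ana
min_clinical: 1
items:
  - {item_id: fever,                predicate: fever,                 weight: 2,  domain: constitutional,   category: clinical}
  - {item_id: leukopenia,           predicate: leucopenia,            weight: 3,  domain: hematologic,      category: clinical}
  - {item_id: thrombocytopenia_aiha, predicate: thrombocytopenia_aiha, weight: 4, domain: hematologic,      category: clinical}
  - {item_id: neuropsychiatric,     predicate: neurological_disorder, weight: 5,  domain: neuropsychiatric, category: clinical}
  - {item_id: alopecia,             predicate: alopecia,              weight: 2,  domain: mucocutaneous,    category: clinical}
  - {item_id: oral_ulcers,          predicate: mucosal_ulcers,        weight: 2,  domain: mucocutaneous,    category: clinical}
  - {item_id: scle_dle,             predicate: scle_dle,              weight: 4,  domain: mucocutaneous,    category: clinical}
  - {item_id: acute_cutaneous,      predicate: malar_rash,            weight: 6,  domain: mucocutaneous,    category: clinical}
  - {item_id: serositis,            predicate: serositis,             weight: 5,  domain: serosal,          category: clinical}
  - {item_id: arthritis,            predicate: arthritis,             weight: 6,  domain: musculoskeletal,  category: clinical}
  - {item_id: proteinuria,          predicate: proteinuria,           weight: 4,  domain: renal,            category: clinical}
  - {item_id: biopsy_nephritis,     predicate: biopsy_proven_nephritis, weight: 10, domain: renal,          category: clinical}
  - {item_id: antiphospholipid,     predicate: antiphospholipid,      weight: 2,  domain: antiphospholipid, category: immunologic}
  - {item_id: low_c3_and_c4,        predicate: low_c3_c4,             weight: 4,  domain: complement,       category: immunologic}
  - {item_id: sle_antibodies,       predicate: "or(anti_dsdna, anti_sm, immunologic_disorder)", weight: 6, domain: sle_antibodies, category: immunologic}
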