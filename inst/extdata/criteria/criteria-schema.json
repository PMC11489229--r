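{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "SLEclassify criteria definition",
  "description": "Schema for declarative classification criteria definition files (YAML or JSON). Predicates are boolean expressions over the declared feature vocabulary using or(...), and(...), not(...).",
  "type": "object",
  "required": ["name", "rule_kind", "threshold", "items"],
  "properties": {
    "name": {"type": "string", "minLength": 1},
    "rule_kind": {
      "enum": ["weighted_sum_threshold", "count_threshold", "domain_weighted_threshold"]
    },
    "threshold": {"type": "number"},
    "threshold_is_strict": {"type": "boolean", "default": false},
    "entry": {"type": "string", "description": "entry predicate; classification impossible when unsatisfied"},
    "min_clinical": {"type": "integer", "minimum": 0, "default": 0},
    "min_immunologic": {"type": "integer", "minimum": 0, "default": 0},
    "standalone": {
      "type": "array",
      "items": {"type": "string"},
      "description": "predicates each sufficient alone for classification"
    },
    "items": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["item_id", "predicate"],
        "properties": {
          "item_id": {"type": "string", "minLength": 1},
          "predicate": {"type": "string", "minLength": 1},
          "weight": {"type": "number", "default": 1},
          "domain": {"type": "string"},
          "category": {"enum": ["clinical", "immunologic", "none"], "default": "none"}
        }
      }
    },
    "probability_transform": {
      "type": "object",
      "required": ["intercept", "coefficients"],
      "properties": {
        "intercept": {"type": "number"},
        "coefficients": {
          "type": "object",
          "additionalProperties": {"type": "number"},
          "description": "item_id -> logistic coefficient; probability = 100 * invlogit(intercept + sum(coef * item indicator))"
        }
      }
    },
    "category_cutpoints": {
      "type": "array",
      "items": {"type": "number"},
      "minItems": 3,
      "maxItems": 3,
      "default": [15, 44, 87]
    }
  }
}
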