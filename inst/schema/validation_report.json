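{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "mirquant validation report",
  "type": "object",
  "required": ["drug", "mode", "seed", "linearity", "accuracy",
               "precision", "lod_loq", "robustness", "assay"],
  "properties": {
    "drug": {"type": "string"},
    "mode": {"enum": ["transmittance", "reflectance"]},
    "seed": {"type": "integer"},
    "linearity": {
      "type": "object",
      "required": ["slope", "intercept", "r2", "n_points", "conc_range"],
      "properties": {
        "slope": {"type": "number"},
        "intercept": {"type": "number"},
        "r2": {"type": "number", "minimum": 0, "maximum": 1},
        "n_points": {"type": "integer"},
        "conc_range": {"type": "array", "items": {"type": "number"},
                       "minItems": 2, "maxItems": 2}
      }
    },
    "accuracy": {
      "oneOf": [
        {"const": "not performed"},
        {"type": "array",
         "items": {
           "type": "object",
           "required": ["cu", "ca", "cv_mean", "recovery_overall",
                        "recovery_standard_addition", "rsd"],
           "properties": {
             "cu": {"type": "number"},
             "ca": {"type": "number"},
             "cv_mean": {"type": "number"},
             "recovery_overall": {"type": "number"},
             "recovery_standard_addition": {"type": "number"},
             "rsd": {"type": "number"}
           }
         }}
      ]
    },
    "precision": {
      "oneOf": [
        {"const": "not performed"},
        {"type": "object",
         "required": ["per_level", "per_day"],
         "properties": {
           "per_level": {"type": "array"},
           "per_day": {"type": "array"}
         }}
      ]
    },
    "lod_loq": {
      "oneOf": [
        {"const": "not performed"},
        {"type": "object",
         "required": ["lod", "loq", "sigma_intercept"],
         "properties": {
           "lod": {"type": "number", "minimum": 0},
           "loq": {"type": "number", "minimum": 0},
           "sigma_intercept": {"type": "number", "minimum": 0}
         }}
      ]
    },
    "robustness": {
      "oneOf": [
        {"const": "not performed"},
        {"type": "object",
         "required": ["summary"],
         "properties": {"summary": {"type": "array"}}}
      ]
    },
    "assay": {
      "oneOf": [
        {"const": "not performed"},
        {"type": "object",
         "required": ["amount_found_mg", "label_claim_mg", "purity_pct"],
         "properties": {
           "amount_found_mg": {"type": "number"},
           "amount_found_sd": {"type": "number"},
           "label_claim_mg": {"type": "number"},
           "purity_pct": {"type": "number"},
           "purity_sd": {"type": "number"},
           "n": {"type": "integer"}
         }}
      ]
    }
  }
}
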