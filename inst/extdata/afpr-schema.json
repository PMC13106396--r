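{
  "$comment": "AI Fairness Provenance Record schema, version 1.0. Interpreted subset of JSON Schema: type, required, properties, items, pattern.",
  "type": "object",
  "required": ["schema_version", "created", "data_provenance", "model_development", "inference_log", "chain_head"],
  "properties": {
    "schema_version": {"type": "string"},
    "created": {"type": "string"},
    "data_provenance": {
      "type": "object",
      "required": ["source", "feature_descriptions", "demographic_composition", "known_limitations"],
      "properties": {
        "source": {"type": "string"},
        "n_patients": {"type": "integer"},
        "seed": {"type": "integer"},
        "feature_descriptions": {"type": "object"},
        "demographic_composition": {
          "type": "object",
          "properties": {
            "male_fraction": {"type": "number"},
            "comorbidity_prevalence": {"type": "number"},
            "outcome_prevalence": {"type": "number"}
          }
        },
        "known_limitations": {"type": "array", "items": {"type": "string"}}
      }
    },
    "model_development": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["sequence", "timestamp", "config"],
        "properties": {
          "sequence": {"type": "integer"},
          "timestamp": {"type": "string"},
          "config": {"type": "object"},
          "metrics": {"type": "object"},
          "rationale": {"type": "string"}
        }
      }
    },
    "inference_log": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["sequence", "entry_id", "timestamp", "model_version", "patient_ref", "payload", "prev_hash", "entry_hash"],
        "properties": {
          "sequence": {"type": "integer"},
          "entry_id": {"type": "string"},
          "timestamp": {"type": "string"},
          "model_version": {"type": "string", "pattern": "^[0-9a-f]{64}$"},
          "patient_ref": {"type": "string"},
          "payload": {
            "type": "object",
            "required": ["model_version", "probability", "predicted_class"],
            "properties": {
              "model_version": {"type": "string"},
              "probability": {"type": "number"},
              "predicted_class": {"type": "integer"},
              "threshold": {"type": "number"},
              "timestamp": {"type": "string"},
              "inputs": {"type": "object"},
              "mechanism": {"type": "object"}
            }
          },
          "prev_hash": {"type": "string", "pattern": "^[0-9a-f]{64}$"},
          "entry_hash": {"type": "string", "pattern": "^[0-9a-f]{64}$"}
        }
      }
    },
    "audit": {
      "type": "object",
      "properties": {
        "fairness": {
          "type": "object",
          "required": ["kind", "n", "threshold", "groups", "DPD"],
          "properties": {
            "kind": {"type": "string"},
            "n": {"type": "integer"},
            "threshold": {"type": "number"},
            "DPD": {"type": "number"},
            "EOD": {"type": "number"},
            "groups": {
              "type": "array",
              "items": {
                "type": "object",
                "required": ["group", "n", "TP", "FP", "TN", "FN", "selection_rate"]
              }
            }
          }
        },
        "permutation": {
          "type": "object",
          "required": ["kind", "observed", "n_permutations", "exceedances", "p_value", "label"]
        },
        "cv": {
          "type": "object",
          "required": ["kind", "model", "k", "folds", "summary"]
        },
        "counterfactual": {
          "type": "object",
          "required": ["kind", "threshold", "margin", "n_boundary", "n_flipped"]
        },
        "sensitivity": {
          "type": "object",
          "required": ["kind", "rows"]
        }
      }
    },
    "chain_head": {"type": "string", "pattern": "^[0-9a-f]{64}$"}
  }
}
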