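{
  "title": "fedcohort experiment configuration",
  "type": "object",
  "required": ["seed"],
  "properties": {
    "profiles": { "type": ["string", "array"] },
    "schema": { "type": ["string", "array"] },
    "outcome_model": { "type": ["string", "object"] },
    "families": { "type": "array", "item_enum": ["lasso", "mlp"] },
    "strategies": { "type": "array", "item_enum": ["local", "pooled", "federated"] },
    "balancing": {
      "type": "string",
      "enum": ["none", "undersample_majority", "oversample_minority", "class_weight"]
    },
    "train": {
      "type": "object",
      "properties": {
        "learning_rate": { "type": "number", "exclusiveMinimum": 0 },
        "batch_size": { "type": "number", "minimum": 0 },
        "l1_lambda": { "type": "number", "minimum": 0 },
        "optimizer": { "type": "string", "enum": ["adam", "sgd"] }
      }
    },
    "federation": {
      "type": "object",
      "properties": {
        "rounds": { "type": ["number", "null"], "minimum": 1 },
        "local_epochs": { "type": "number", "minimum": 1 },
        "noise_sigma": { "type": "number", "minimum": 0 }
      }
    },
    "bootstrap": {
      "type": "object",
      "properties": {
        "n_iterations": { "type": "number", "minimum": 1 },
        "test_fraction": { "type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1 }
      }
    },
    "seed": { "type": "number" }
  }
}
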