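{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "turbicell run configuration",
  "type": "object",
  "additionalProperties": false,
  "required": ["plates"],
  "properties": {
    "hours": {"type": "number", "minimum": 0},
    "controller": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "x_set": {"type": "number", "exclusiveMinimum": 0},
        "y_max": {"type": "number", "exclusiveMinimum": 0},
        "dt_hours": {"type": "number", "exclusiveMinimum": 0},
        "alpha": {"type": "number", "minimum": 0, "maximum": 1},
        "k_init": {"type": "number", "minimum": 0}
      }
    },
    "noise": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "od_cv": {"type": "number", "minimum": 0},
        "vol_cv": {"type": "number", "minimum": 0},
        "seed": {"type": "integer"}
      }
    },
    "plates": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "additionalProperties": false,
        "required": ["plate"],
        "properties": {
          "plate": {"type": "string"},
          "od0": {"type": "number", "minimum": 0},
          "volume_ul": {"type": "number", "exclusiveMinimum": 0},
          "k": {"type": "number", "minimum": 0},
          "expression_factor": {"type": "number", "minimum": 0},
          "rows": {"type": "integer", "minimum": 1, "maximum": 26},
          "cols": {"type": "integer", "minimum": 1}
        }
      }
    }
  }
}
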