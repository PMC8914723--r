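{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "nirfm pipeline configuration",
  "type": "object",
  "additionalProperties": false,
  "required": ["seed", "simulate", "split", "model"],
  "properties": {
    "seed": { "type": "integer" },
    "simulate": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "grid_points": { "type": "integer", "minimum": 2 },
        "counts": {
          "type": "object",
          "description": "material preset name -> sample count",
          "additionalProperties": { "type": "integer", "minimum": 0 }
        }
      }
    },
    "preprocess": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "method": { "enum": ["raw", "mean", "max", "range", "snv", "msc", "sg1", "sg2"] },
        "window": { "type": "integer" },
        "polyorder": { "type": "integer" },
        "reference": { "type": "array", "items": { "type": "number" } }
      }
    },
    "split": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "fraction": { "type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1 }
      }
    },
    "model": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "max_lv": { "type": "integer", "minimum": 1 },
        "folds": { "type": "integer", "minimum": 2 },
        "autoscale": { "type": "boolean" }
      }
    },
    "selection": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "wrc": { "type": "object" },
        "vip": { "type": "object" },
        "sfs": { "type": "object" },
        "spa": { "type": "object" },
        "ipls": { "type": "object" }
      }
    },
    "imaging": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "enabled": { "type": "boolean" },
        "n_scenes": { "type": "integer", "minimum": 1 },
        "lines": { "type": "integer", "minimum": 8 },
        "pixels": { "type": "integer", "minimum": 8 },
        "combinations": {
          "type": "array",
          "items": { "type": "array", "items": { "type": "number" } }
        },
        "min_blob": { "type": "integer", "minimum": 1 },
        "median_filter": { "type": "boolean" }
      }
    }
  }
}
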