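{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "tdcsfc study report",
  "type": "object",
  "required": ["subjects", "group", "provenance"],
  "properties": {
    "subjects": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "pre", "post"],
        "properties": {
          "id": {"type": "string"},
          "pre": {"type": "object"},
          "post": {"type": "object"},
          "seed_left_mm": {"type": "array"},
          "seed_right_mm": {"type": "array"}
        }
      }
    },
    "group": {
      "type": "object",
      "required": ["interhemispheric_z", "ic_left", "ic_right",
                   "lcor_left", "lcor_right"],
      "additionalProperties": {
        "type": "object",
        "required": ["t", "df", "p"],
        "properties": {
          "t": {"type": "number"},
          "df": {"type": "integer"},
          "p": {"type": "number", "minimum": 0, "maximum": 1}
        }
      }
    },
    "clusters": {"type": ["array", "object", "null"]},
    "efield": {
      "type": ["object", "null"],
      "properties": {
        "roi_mean": {"type": "array", "items": {"type": "number"}},
        "brain_mean": {"type": "array", "items": {"type": "number"}}
      }
    },
    "regressions": {"type": ["object", "null"]},
    "provenance": {
      "type": "object",
      "required": ["config", "config_hash", "master_seed", "package_version"],
      "properties": {
        "config_hash": {"type": "integer"},
        "master_seed": {"type": "integer"},
        "package_version": {"type": "string"},
        "r_version": {"type": "string"}
      }
    }
  }
}
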