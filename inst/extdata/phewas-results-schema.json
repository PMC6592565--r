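{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "PRS-PheWAS results payload",
  "type": "object",
  "required": ["prs", "n_studies", "bonferroni_threshold", "results"],
  "properties": {
    "prs": {
      "type": "object",
      "description": "Provenance of the polygenic score (trait, method tag, ...)"
    },
    "n_studies": {"type": "integer", "minimum": 1},
    "bonferroni_threshold": {"type": "number", "exclusiveMinimum": 0},
    "results": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["phecode", "description", "group", "n_case",
                     "n_control", "neglog10_p", "direction", "or",
                     "or_lower", "or_upper", "bonferroni_significant",
                     "flagged"],
        "properties": {
          "phecode": {"type": "string"},
          "description": {"type": "string"},
          "group": {"type": "string"},
          "n_case": {"type": "integer"},
          "n_control": {"type": "integer"},
          "neglog10_p": {"type": ["number", "null"]},
          "direction": {"enum": ["up", "down"]},
          "or": {"type": "number"},
          "or_lower": {"type": "number"},
          "or_upper": {"type": "number"},
          "bonferroni_significant": {"type": "boolean"},
          "flagged": {"type": "boolean"}
        }
      }
    }
  }
}
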