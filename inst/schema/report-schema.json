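{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "connplast pipeline report",
  "type": "object",
  "required": ["summary", "provenance"],
  "properties": {
    "summary": {
      "type": "object",
      "properties": {
        "lateralization": {
          "type": ["array", "null"],
          "items": {
            "type": "object",
            "required": ["timepoint", "estimate", "t", "df", "p", "n"]
          }
        },
        "strength_contrasts": {
          "type": ["array", "null"],
          "items": {
            "type": "object",
            "required": ["measure", "period", "estimate", "se", "t", "df", "p"]
          }
        },
        "behavioral": {"type": ["array", "null"]},
        "vocabulary_correlation": {"type": ["array", "null"]}
      }
    },
    "omnibus": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["component", "direction", "extent", "statistic_value",
                     "p_fwe", "significant"]
      }
    },
    "omnibus_components": {"type": ["array", "null"]},
    "posthoc": {"type": ["array", "null"]},
    "score_nbs": {"type": ["array", "null"]},
    "score_nbs_components": {"type": ["array", "null"]},
    "subgroup": {"type": ["object", "null"]},
    "skipped": {"type": ["array", "null"], "items": {"type": "string"}},
    "provenance": {
      "type": "object",
      "required": ["package_version", "seed", "fraction", "config_hash"]
    }
  }
}
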