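{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "baculoscribe pipeline report",
  "type": "object",
  "required": ["genome_id", "parameters", "stats", "promoters"],
  "properties": {
    "genome_id": { "type": "string" },
    "parameters": {
      "type": "object",
      "required": ["min_aa", "max_overlap_bp", "window"]
    },
    "stats": {
      "type": "object",
      "required": ["length_bp", "gc_percent", "orf_count",
                   "forward_count", "reverse_count",
                   "coding_fraction_percent"],
      "properties": {
        "length_bp": { "type": "integer" },
        "gc_percent": { "type": "number" },
        "orf_count": { "type": "integer" },
        "forward_count": { "type": "integer" },
        "reverse_count": { "type": "integer" },
        "coding_fraction_percent": { "type": "number" }
      }
    },
    "hrs": { "type": ["array", "null"] },
    "promoters": { "type": "object" },
    "comparative": { "type": "object" },
    "demarcation": { "type": "object" }
  }
}
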