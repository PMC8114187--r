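{
  "$id": "flowkern/provenance.schema.json",
  "version": 1,
  "title": "flowkern provenance document",
  "type": "object",
  "required": ["version", "jobs"],
  "additionalProperties": false,
  "properties": {
    "version": {"type": "integer"},
    "jobs": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["job", "rule", "inputs", "outputs", "action",
                     "environment"],
        "properties": {
          "job": {"type": "string"},
          "rule": {"type": "string"},
          "binding": {"type": "object"},
          "inputs": {"type": "array"},
          "outputs": {"type": "array"},
          "params": {"type": "object"},
          "action": {"type": "string"},
          "environment": {"type": "string"},
          "start": {},
          "end": {},
          "seconds": {},
          "max_rss": {},
          "cache_digest": {},
          "cache_hit": {"type": "boolean"}
        }
      }
    }
  }
}
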