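{
  "$id": "flowkern/workflow.schema.json",
  "version": 1,
  "title": "flowkern workflow document",
  "type": "object",
  "required": ["rules"],
  "additionalProperties": false,
  "properties": {
    "config": {"type": "object"},
    "ruleorder": {"type": "array"},
    "rules": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "additionalProperties": false,
        "properties": {
          "input": {},
          "output": {},
          "params": {"type": "object"},
          "priority": {"type": "integer"},
          "resources": {"type": "object"},
          "group": {"type": "string"},
          "temp": {"type": "array"},
          "stream": {"type": "array"},
          "cache": {"type": "boolean"},
          "checkpoint": {"type": "boolean"},
          "shell": {"type": "string"},
          "env": {"type": "string"},
          "log": {"type": "string"},
          "wildcard_constraints": {"type": "object"}
        }
      }
    }
  }
}
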