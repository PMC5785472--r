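{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "pksline stage report",
  "type": "object",
  "required": ["stage", "payload", "provenance"],
  "properties": {
    "stage": {"type": "string", "minLength": 1},
    "payload": {"type": "object"},
    "provenance": {
      "type": "object",
      "required": ["inputs", "config_hash", "seed"],
      "properties": {
        "inputs": {"type": "array", "items": {"type": "string"}},
        "config_hash": {"type": "string"},
        "seed": {"type": ["integer", "null"]}
      }
    }
  }
}
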