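{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Between-group comparison result",
  "type": "object",
  "required": ["test_name", "statistic", "p_value", "group_ids"],
  "properties": {
    "test_name": {"type": "string",
                  "enum": ["kruskal_wallis", "rate_test", "curve_wald"]},
    "statistic": {"type": "number"},
    "p_value": {"type": "number", "minimum": 0, "maximum": 1},
    "group_ids": {"type": "array", "items": {"type": "string"}},
    "dose_gy": {"type": ["number", "null"]},
    "endpoint": {"type": ["string", "null"]}
  }
}
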