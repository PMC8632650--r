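{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Absorbed-dose estimate with Merkle uncertainty bounds",
  "type": "object",
  "required": ["dose_gy", "lower_gy", "upper_gy", "observed_count",
               "n_cells", "observed_yield", "conf_count", "conf_curve",
               "curve_endpoint"],
  "properties": {
    "dose_gy": {"type": "number", "minimum": 0},
    "lower_gy": {"type": "number", "minimum": 0},
    "upper_gy": {"type": "number", "minimum": 0},
    "observed_count": {"type": "integer", "minimum": 0},
    "n_cells": {"type": "integer", "minimum": 1},
    "observed_yield": {"type": "number", "minimum": 0},
    "conf_count": {"type": "number", "minimum": 0, "maximum": 1},
    "conf_curve": {"type": "number", "minimum": 0, "maximum": 1},
    "curve_endpoint": {"type": "string",
                       "enum": ["dicentrics", "dicentrics_rings", "dsb"]},
    "open_upper": {"type": "boolean"},
    "extrapolated": {"type": "boolean"}
  }
}
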