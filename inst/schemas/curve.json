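{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Linear-quadratic dose-response curve",
  "type": "object",
  "required": ["endpoint", "C", "alpha", "beta", "se_C", "se_alpha",
               "se_beta", "vcov", "dispersion_scale"],
  "properties": {
    "endpoint": {"type": "string",
                 "enum": ["dicentrics", "dicentrics_rings", "dsb"]},
    "C": {"type": "number", "minimum": 0},
    "alpha": {"type": "number", "minimum": 0},
    "beta": {"type": "number", "minimum": 0},
    "se_C": {"type": "number", "minimum": 0},
    "se_alpha": {"type": "number", "minimum": 0},
    "se_beta": {"type": "number", "minimum": 0},
    "vcov": {"type": "array", "minItems": 9, "maxItems": 9,
             "items": {"type": "number"},
             "description": "3x3 variance-covariance over (C, alpha, beta), row-major"},
    "dispersion_scale": {"type": "number", "minimum": 0},
    "alpha_beta_ratio": {"type": ["number", "null"]}
  }
}
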