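{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "spadspec machine-readable reports",
  "oneOf": [
    {
      "title": "fit report",
      "type": "object",
      "required": ["n_calibration", "n_validation", "selected_wavelengths",
                   "n_components", "calibration"],
      "properties": {
        "n_calibration": {"type": "integer", "minimum": 2},
        "n_validation": {"type": "integer", "minimum": 0},
        "selected_wavelengths": {"type": "array", "items": {"type": "number"}},
        "n_components": {"type": "integer", "minimum": 1},
        "calibration": {"$ref": "#/definitions/metrics"},
        "validation": {"$ref": "#/definitions/metrics"}
      }
    },
    {
      "title": "predict summary",
      "type": "object",
      "required": ["mean_spad", "min", "max", "n_pixels", "otsu_threshold",
                   "alpha"],
      "properties": {
        "mean_spad": {"type": "number"},
        "min": {"type": "number"},
        "max": {"type": "number"},
        "n_pixels": {"type": "integer", "minimum": 1},
        "otsu_threshold": {"type": "integer", "minimum": 0, "maximum": 254},
        "alpha": {"type": "number"}
      }
    }
  ],
  "definitions": {
    "metrics": {
      "type": "object",
      "required": ["r2", "rmse", "rpd", "n", "grade"],
      "properties": {
        "r2": {"type": "number"},
        "rmse": {"type": "number", "minimum": 0},
        "rpd": {"type": "number", "minimum": 0},
        "n": {"type": "integer", "minimum": 2},
        "grade": {"enum": ["good", "middle", "poor"]}
      }
    }
  }
}
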