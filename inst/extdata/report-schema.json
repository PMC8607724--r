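{
  "type": "object",
  "required": ["schema_version", "settings", "n_records", "n_deliverable", "spc"],
  "properties": {
    "schema_version": {"type": "string"},
    "settings": {
      "type": "object",
      "required": ["deliverability_cut", "baseline_size", "n_boot", "seed"],
      "properties": {
        "threshold_percent": {"type": "number"},
        "deliverability_cut": {"type": "number"},
        "baseline_size": {"type": "number"},
        "n_boot": {"type": "number"},
        "seed": {"type": "number"}
      }
    },
    "n_records": {"type": "number"},
    "n_deliverable": {"type": "number"},
    "spc": {
      "type": "object",
      "required": ["period_boundaries", "periods"],
      "properties": {
        "periods": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["n", "x_bar", "sigma", "mr_bar", "al_cs", "tl_cs",
                         "ci_al", "ci_tl", "in_control"],
            "properties": {
              "n": {"type": "number"},
              "x_bar": {"type": "number"},
              "sigma": {"type": "number"},
              "mr_bar": {"type": "number"},
              "al_cs": {"type": "number"},
              "tl_cs": {"type": "number"},
              "in_control": {"type": "boolean"}
            }
          }
        }
      }
    }
  }
}
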