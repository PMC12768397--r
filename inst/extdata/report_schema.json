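{
  "type": "object",
  "required_properties": {
    "config": {
      "type": "object",
      "required_properties": {
        "seed": {"type": "number"},
        "n": {"type": "number"},
        "mode": {"type": "string"}
      }
    },
    "efa": {
      "type": "object",
      "required_properties": {
        "resilience": {
          "type": "object",
          "required_properties": {
            "kmo": {"type": "number"},
            "var_explained": {"type": "number"}
          }
        },
        "stress": {
          "type": "object",
          "required_properties": {
            "kmo": {"type": "number"},
            "var_explained": {"type": "number"}
          }
        }
      }
    },
    "cfa": {
      "type": "object",
      "required_properties": {
        "stress": {
          "type": "object",
          "required_properties": {
            "fit": {
              "type": "object",
              "required_properties": {
                "chisq": {"type": "number"},
                "df": {"type": "number"},
                "cfi": {"type": "number"},
                "rmsea": {"type": "number"},
                "srmr": {"type": "number"}
              }
            }
          }
        },
        "resilience": {
          "type": "object",
          "required_properties": {
            "fit": {
              "type": "object",
              "required_properties": {
                "chisq": {"type": "number"},
                "df": {"type": "number"},
                "cfi": {"type": "number"},
                "rmsea": {"type": "number"},
                "srmr": {"type": "number"}
              }
            }
          }
        }
      }
    },
    "reliability": {"type": "object", "required_properties": {}},
    "validity": {
      "type": "object",
      "required_properties": {"htmt_max": {"type": "number"}}
    },
    "invariance": {"type": "array"},
    "weights": {"type": "array"},
    "comparison": {"type": "array"},
    "log": {"type": "array"}
  }
}
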