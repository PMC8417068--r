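{
  "example_ikr_blocker": {
    "c_eff": 2.0,
    "channels": {
      "IKr": {"ic50": 20.0, "h": 1.0}
    }
  },
  "example_balanced_blocker": {
    "c_eff": 100.0,
    "channels": {
      "IKr": {"ic50": 1500.0, "h": 0.9},
      "ICaL": {"ic50": 800.0, "h": 0.7}
    }
  },
  "example_ical_blocker": {
    "c_eff": 120.0,
    "channels": {
      "ICaL": {"ic50": 750.0, "h": 0.7}
    }
  },
  "_comment": "Illustrative placeholder Hill parameters for exercising the pipeline; NOT measured patch-clamp values for any real drug."
}
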