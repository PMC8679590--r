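{
  "km": {"mouse": 3, "cynomolgus": 12, "human": 37},
  "reference_weight_kg": {"mouse": 0.025, "human": 60},
  "human_bsa_m2": 1.89
}
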