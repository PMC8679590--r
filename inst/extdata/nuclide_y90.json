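{"name": "90Y", "half_life_h": 64, "mean_energy_mev": 0.9337}
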