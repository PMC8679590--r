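{"red_marrow_mgy": 3000, "other_organ_mgy": 20000}
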