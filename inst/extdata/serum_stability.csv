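agent,time_h,mean_pct,sd_pct
y90_ff21101,3,96.9,0.2
y90_ff21101,24,94.7,0.3
y90_ff21101,48,94.3,0.4
y90_ff21101,96,93.7,0.7
in111_ff21101,3,99.8,0.2
in111_ff21101,24,99.3,1.5
in111_ff21101,48,99.3,0.2
in111_ff21101,96,98.1,1.5
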