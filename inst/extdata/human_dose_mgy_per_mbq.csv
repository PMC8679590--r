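organ,antibody_dose_mg_per_kg,mgy_per_mbq
heart_wall,0.04,2.31
liver,0.04,2.56
lungs,0.04,1.21
red_marrow,0.04,0.661
osteogenic_cells,0.04,0.680
spleen,0.04,12.0
total_body,0.04,0.382
heart_wall,0.4,2.54
liver,0.4,2.47
lungs,0.4,1.19
red_marrow,0.4,0.786
osteogenic_cells,0.4,0.817
spleen,0.4,6.93
total_body,0.4,0.423
heart_wall,4,3.28
liver,4,2.55
lungs,4,1.82
red_marrow,4,0.885
osteogenic_cells,4,0.912
spleen,4,2.77
total_body,4,0.459
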