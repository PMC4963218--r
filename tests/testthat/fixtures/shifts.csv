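entry_id,residue,nucleus,value_ppm,reference_standard
e1,LYS,CE,41.90,DSS
e2,LYS,CE,43.55,TMS
e3,LYS,CE,41.70,TSP
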