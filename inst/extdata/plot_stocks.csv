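plot,pool,kg_c_m2,se
HSC,pj_tree,0.0003,NA
HSC,sagebrush,0.41,0.01
HSC,grass,0.006,0.002
HSC,duff_litter,0.05,0.01
HSC,mineral_soil,1.52,0.06
LD,pj_tree,1.13,NA
LD,sagebrush,0.31,0.03
LD,grass,0.006,0.001
LD,duff_litter,0.42,0.11
LD,mineral_soil,1.68,0.07
HD,pj_tree,3.24,NA
HD,sagebrush,0.17,0.02
HD,grass,0.001,0.0006
HD,duff_litter,0.71,0.13
HD,mineral_soil,1.37,0.05
PJD,pj_tree,1.10,NA
PJD,sagebrush,0.31,0.02
PJD,grass,0.011,0.001
PJD,duff_litter,0.53,0.14
PJD,mineral_soil,1.44,0.06
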