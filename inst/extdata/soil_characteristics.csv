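plot,n_samples,mineral_bd_g_cm3,mineral_bd_se,duff_bd_g_cm3,duff_bd_se,duff_depth_cm,duff_depth_se,soil_co3_pct,soil_co3_se
HSC,32,1.55,0.02,0.13,0.004,0.38,0.03,1.97,0.69
LD,34,1.38,0.02,0.25,0.03,1.53,0.45,1.17,0.04
HD,41,1.29,0.02,0.27,0.04,2.13,0.35,2.99,0.84
PJD,34,1.38,0.02,0.22,0.02,2.09,0.46,0.96,0.07
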