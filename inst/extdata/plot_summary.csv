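plot,live_density_stems_ha,n_trees,n_pinon,n_juniper,mean_age_yr,mean_bca_m2,mean_rcd_cm,grass_cover_pct,sagebrush_cover_pct,duff_cover_pct,bareground_cover_pct
HSC,133,4,0,4,NA,NA,NA,11.85,37.03,NA,41.38
LD,1033,31,30,1,51,4.2,10.64,11.97,25.62,27.60,31.98
HD,1400,42,37,5,53,5.1,13.70,2.71,14.16,53.84,27.08
PJD,100,30,15,3,47,4.9,8.54,20.41,25.83,25.21,24.58
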