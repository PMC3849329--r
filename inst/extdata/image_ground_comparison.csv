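measurement,LD,HD
image_canopies,32,42
ground_canopies,31,42
image_canopy_area_m2,137.00,235.00
ground_canopy_area_m2,130.05,213.57
image_mean_canopy_area_m2,4.15,5.46
ground_mean_canopy_area_m2,4.19,5.08
image_kg_c_plot,455.12,846.11
ground_kg_c_plot_canopy_allometry,457.98,833.39
ground_kg_c_plot_rcd_allometry,327.26,937.49
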