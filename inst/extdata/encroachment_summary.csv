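quantity,value,unit
image_total_c_mg_25ha,358.93,Mg C per 25 ha
new_trees_per_ha,869,stems per ha of 1937-open area
span_years,69,years between photo dates
fraction_landscape_treeless,0.32,fraction
fraction_open_occupied_2006,0.68,fraction
plot_scaled_ld_mg,267,Mg C per 25 ha
plot_scaled_hd_mg,781,Mg C per 25 ha
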