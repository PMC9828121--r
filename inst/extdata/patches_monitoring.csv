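id,distance_m,nectar_L_per_day,pollen_g_per_day,sucrose_mol_per_L,flower_start,flower_end,treated,water_L_per_day
monitoring_site,1500,8,500,1.5,1,366,FALSE,0
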