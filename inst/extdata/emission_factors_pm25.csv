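cover_type,fire_type,phase,species,ef_g_per_kg
forest,rx,stfs,PM25,17.57
forest,wildfire,stfs,PM25,23.2
shrubland,any,stfs,PM25,7.06
grassland,any,stfs,PM25,8.51
any,any,rsc_woody,PM25,33
any,any,rsc_duff,PM25,35.3
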