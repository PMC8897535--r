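animal,dose_mg_per_kg,cave_ng_per_ml,occupancy_pct,method
NHP1,1.27,338.5,94.1,2tc
NHP1,1.27,338.5,99.4,patlak
NHP2,1.27,370.0,90.8,2tc
NHP2,1.27,370.0,100.5,patlak
NHP3,0.03,0.7,32.0,2tc
NHP3,0.03,0.7,34.8,patlak
NHP3,0.14,10.3,91.5,2tc
NHP3,0.14,10.3,99.3,patlak
NHP4,0.03,2.2,59.9,2tc
NHP4,0.03,2.2,60.4,patlak
NHP4,0.42,45.6,94.1,2tc
NHP4,0.42,45.6,98.8,patlak
NHP5,0.07,10.3,86.3,2tc
NHP5,0.07,10.3,90.9,patlak
NHP5,0.01,,22.8,2tc
NHP5,0.01,,25.4,patlak
NHP6,0.14,9.8,91.1,2tc
NHP6,0.14,9.8,96.4,patlak
NHP7,0.05,51.4,47.8,2tc
NHP7,0.05,51.4,49.9,patlak
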