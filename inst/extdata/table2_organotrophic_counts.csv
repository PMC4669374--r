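hydrocarbon,dose_mg_per_kg,value,letter
naphthalene,0,18.25,a
naphthalene,1000,23.25,b
naphthalene,2000,34.22,c
naphthalene,4000,44.36,d
phenanthrene,0,18.25,a
phenanthrene,1000,22.47,b
phenanthrene,2000,27.67,bc
phenanthrene,4000,31.12,c
anthracene,0,18.25,a
anthracene,1000,32.25,b
anthracene,2000,39.48,c
anthracene,4000,63.70,d
pyrene,0,18.25,a
pyrene,1000,35.72,b
pyrene,2000,50.68,c
pyrene,4000,52.79,c
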