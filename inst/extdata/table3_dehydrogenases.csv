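hydrocarbon,dose_mg_per_kg,value,letter
naphthalene,0,8.62,c
naphthalene,1000,8.93,c
naphthalene,2000,7.25,b
naphthalene,4000,6.21,a
phenanthrene,0,8.62,c
phenanthrene,1000,7.10,b
phenanthrene,2000,6.73,b
phenanthrene,4000,5.15,a
anthracene,0,8.63,b
anthracene,1000,8.73,b
anthracene,2000,8.37,ab
anthracene,4000,7.87,a
pyrene,0,8.63,c
pyrene,1000,8.62,c
pyrene,2000,7.98,b
pyrene,4000,7.16,a
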