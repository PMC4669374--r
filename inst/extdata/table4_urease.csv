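hydrocarbon,dose_mg_per_kg,value,letter
naphthalene,0,2.76,c
naphthalene,1000,2.00,b
naphthalene,2000,1.80,b
naphthalene,4000,1.11,a
phenanthrene,0,2.76,d
phenanthrene,1000,2.43,c
phenanthrene,2000,1.44,b
phenanthrene,4000,1.06,a
anthracene,0,2.76,d
anthracene,1000,1.93,c
anthracene,2000,1.57,b
anthracene,4000,1.18,a
pyrene,0,2.76,d
pyrene,1000,2.22,c
pyrene,2000,1.63,b
pyrene,4000,1.14,a
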