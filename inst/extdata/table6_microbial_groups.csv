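group,unit_cfu_per_kg,treatment,mean,sd
bacteria,1e7,control,115,18
bacteria,1e7,naphthalene,38,4
bacteria,1e7,phenanthrene,90,9
bacteria,1e7,anthracene,154,14
bacteria,1e7,pyrene,43,7
staphylococci,1e3,control,240,22
staphylococci,1e3,naphthalene,430,25
staphylococci,1e3,phenanthrene,250,15
staphylococci,1e3,anthracene,450,21
staphylococci,1e3,pyrene,520,32
molds,1e3,control,9,2
molds,1e3,naphthalene,9,1
molds,1e3,phenanthrene,8,2
molds,1e3,anthracene,36,7
molds,1e3,pyrene,25,4
enterobacteriaceae,1e3,control,9,3
enterobacteriaceae,1e3,naphthalene,3200,10
enterobacteriaceae,1e3,phenanthrene,3300,21
enterobacteriaceae,1e3,anthracene,1600,8
enterobacteriaceae,1e3,pyrene,6200,20
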