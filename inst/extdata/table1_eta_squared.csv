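term,organotrophic_count,dehydrogenases,urease
type,17.35,54.56,0.21
dose,63.59,10.64,95.42
type:dose,13.86,33.66,3.40
error,5.20,1.14,0.96
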