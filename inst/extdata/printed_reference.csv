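id,description,value
t1,RS dehydrogenases pyrene 4000 mg/kg,0.709
t2,RS urease pyrene 2000 mg/kg,0.419
t3,RS urease pyrene 4000 mg/kg,0.260
t4,fold change of pyrene column-mean organotrophic count vs control,2.2
t5,fold change of phenanthrene column-mean organotrophic count vs control,1.4
t6,fold change of pyrene 4000 mg/kg organotrophic count vs control,2.9
t7,mean root-growth inhibition of Sinapis alba over four PAHs (%),28.0
t8,mean seed-germination inhibition by pyrene over three species (%),11.1
t9,mean root-growth inhibition by phenanthrene over three species (%),20.6
t10,average organotrophic count for naphthalene over four doses,30.02
t11,average urease activity for anthracene over four doses,1.86
t12,fold increase of total bacteria under anthracene vs control,1.34
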