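variable,exposed_events,exposed_total,unexposed_events,unexposed_total
age_55_plus,19,152,22,334
male,13,119,24,331
aggressive_variant,6,36,31,414
extrathyroidal_extension,18,127,23,359
pt3_4,21,161,16,287
pn1,26,199,15,287
braf_like,24,260,6,113
high_mutation_burden,21,181,10,203
nmf_cluster3,20,153,19,326
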