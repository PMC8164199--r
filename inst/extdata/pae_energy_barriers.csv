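compound,parent,barrier_kj_mol,reported_rate
DINP,NA,51.77,NA
DEHP,NA,4.08,NA
DINP-C6H5,DINP,5.96,-88.5
DEHP-F,DEHP,0.31,-92.4
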