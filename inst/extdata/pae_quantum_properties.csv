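compound,parent,total_energy,energy_gap,frequency,reported_energy_rate,reported_gap_rate
DINP,NA,-1317.02,5.51,7.60,NA,NA
DEHP,NA,-1238.39,5.56,11.39,NA,NA
DINP-C6H5,DINP,-1233.51,5.18,17.73,-6.34,-5.99
DEHP-F,DEHP,-1298.30,5.49,5.44,4.84,-1.26
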