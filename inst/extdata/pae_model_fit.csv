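set,compound,fit_value,estimated,active,reported_error
training,DINP,5.92,0.72,0.79,-1.10
training,DEHP,5.91,0.74,0.792,-1.06
training,BDP,5.88,0.79,0.797,-1.01
training,BOP,5.87,0.80,0.82,-1.03
training,HEHP,5.87,0.81,0.798,1.01
training,DNOP,5.86,0.82,0.792,1.03
training,DPP,5.85,0.84,0.936,-1.11
training,BMPP,5.84,0.87,0.829,1.05
training,DCHP,5.82,0.90,0.845,1.07
training,BCHP,5.74,1.09,1.0,1.09
test,DIDP,5.96,0.66,0.79,-1.20
test,DUP,5.85,0.84,0.79,1.06
test,DNDP,5.82,0.90,0.79,1.13
test,DIPP,5.77,1.02,0.985,1.03
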