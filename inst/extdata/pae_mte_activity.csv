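parent_id,derivative_id,substituent,estimated_parent,estimated_derivative,reported_rate
DINP,DINP-CH3,-CH3,0.7171,0.8214,14.54
DINP,DINP-CH2CH3,-CH2CH3,0.7171,0.6997,-2.43
DINP,DINP-CH2CH2CH3,-CH2CH2CH3,0.7171,0.8028,11.95
DINP,DINP-CH=CH2,-CH=CH2,0.7171,0.8247,15.00
DINP,DINP-C6H5,-C6H5,0.7171,0.8124,13.29
DINP,DINP-OCH3,-OCH3,0.7171,1.1392,58.86
DINP,DINP-Cl,-Cl,0.7171,0.6761,-5.72
DINP,DINP-F,-F,0.7171,1.0018,39.70
DINP,DINP-Br,-Br,0.7171,0.9851,37.37
DINP,DINP-SH,-SH,0.7171,2.2095,208.12
DINP,DINP-NO2,-NO2,0.7171,1.6933,136.13
DEHP,DEHP-CH3,-CH3,0.7441,0.7442,0.01
DEHP,DEHP-CH2CH3,-CH2CH3,0.7441,1.0099,35.72
DEHP,DEHP-CH2CH2CH3,-CH2CH2CH3,0.7441,0.7456,0.20
DEHP,DEHP-CH=CH2,-CH=CH2,0.7441,0.8410,13.02
DEHP,DEHP-C6H5,-C6H5,0.7441,0.8641,16.13
DEHP,DEHP-OCH3,-OCH3,0.7441,1.1018,48.07
DEHP,DEHP-Cl,-Cl,0.7441,0.7906,6.25
DEHP,DEHP-F,-F,0.7441,0.9070,21.89
DEHP,DEHP-Br,-Br,0.7441,0.8554,14.96
DEHP,DEHP-SH,-SH,0.7441,0.7712,3.64
DEHP,DEHP-NO2,-NO2,0.7441,0.8929,20.00
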