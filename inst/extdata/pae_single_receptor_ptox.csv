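compound,parent,green_algae,daphnid,mysid,fish,reported_green_algae,reported_daphnid,reported_mysid,reported_fish
DINP,NA,2.3039,1.3371,3.0064,1.8487,NA,NA,NA,NA
DINP-CH3,DINP,2.0049,2.0082,1.9758,2.3857,-12.98,50.19,-34.28,29.05
DINP-CH2CH2CH3,DINP,2.1938,2.9862,2.4324,1.3578,-4.78,123.33,-19.09,-26.55
DINP-CH=CH2,DINP,1.2773,2.4678,2.9583,1.1800,-44.56,84.56,-1.60,-36.17
DINP-C6H5,DINP,2.1943,0.394,2.0074,0.7200,-4.76,-70.53,-33.23,-61.05
DINP-OCH3,DINP,2.1396,1.9394,2.2089,3.1838,-7.13,45.05,-26.52,72.23
DINP-F,DINP,1.4256,2.3887,1.9745,3.1892,-38.12,78.65,-34.32,72.52
DINP-Br,DINP,1.3281,1.100,2.4098,2.4892,-42.35,-17.73,-19.84,34.65
DINP-SH,DINP,1.6563,5.5234,1.9857,1.5304,-28.11,313.09,-33.95,-17.21
DINP-NO2,DINP,1.7235,1.1611,2.1128,2.1955,-25.19,-13.16,-29.72,18.77
DEHP,NA,2.4583,2.5771,2.5511,1.2037,NA,NA,NA,NA
DEHP-OCH3,DEHP,2.0141,5.3772,1.9799,1.2720,-18.07,108.65,-22.39,5.67
DEHP-F,DEHP,2.3623,2.2673,2.2677,0.7456,-3.91,-12.02,-11.11,-38.06
DEHP-Br,DEHP,1.7537,1.9605,5.0185,0.9164,-28.66,-23.93,96.73,-23.87
DEHP-NO2,DEHP,1.9213,0.7316,2.7852,0.4750,-21.85,-71.61,9.18,-60.54
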