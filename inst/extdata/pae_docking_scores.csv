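compound,parent,protein,score,reported_rate
DINP,NA,1BA9,97.701,NA
DINP,NA,3DWV,66.242,NA
DINP,NA,3ZXX,74.518,NA
DINP,NA,3KDT,142.43,NA
DEHP,NA,1BA9,72.054,NA
DEHP,NA,3DWV,56.532,NA
DEHP,NA,3ZXX,63.789,NA
DEHP,NA,3KDT,82.86,NA
DINP-C6H5,DINP,1BA9,83.904,-14.1
DINP-C6H5,DINP,3DWV,59.264,-10.5
DINP-C6H5,DINP,3ZXX,68.658,-7.9
DINP-C6H5,DINP,3KDT,114.19,-19.8
DEHP-F,DEHP,1BA9,58.184,-19.2
DEHP-F,DEHP,3DWV,53.211,-5.9
DEHP-F,DEHP,3ZXX,58.610,-8.1
DEHP-F,DEHP,3KDT,79.66,-3.9
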