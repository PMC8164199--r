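compound,parent,green_algae,daphnid,mysid,fish,reported_green_algae,reported_daphnid,reported_mysid,reported_fish
DINP,NA,3.5654,2.6990,4.2790,2.6990,NA,NA,NA,NA
DINP-CH3,DINP,1.2218,0.5784,1.4949,0.7100,-65.73,-78.57,-65.07,-73.70
DINP-CH2CH2CH3,DINP,1.8861,1.1612,2.3010,1.2441,-47.10,-56.98,-46.23,-53.90
DINP-CH=CH2,DINP,1.4559,0.7852,1.7696,0.8996,-59.16,-70.91,-58.65,-66.67
DINP-C6H5,DINP,2.0000,1.2676,2.3979,1.3468,-43.91,-53.03,-43.96,-50.10
DINP-OCH3,DINP,0.3251,-0.2350,0.4425,-0.0453,-90.88,-108.71,-89.66,-101.68
DINP-F,DINP,0.8356,0.2262,1.0410,0.3830,-76.56,-91.62,-75.67,-85.81
DINP-Br,DINP,1.0410,0.4056,1.3010,0.5436,-70.80,-84.97,-69.59,-79.86
DINP-SH,DINP,0.8182,0.2097,1.0223,0.3665,-77.05,-92.23,-76.11,-86.42
DINP-NO2,DINP,0.2336,-0.3193,0.3372,-0.1248,-93.45,-111.83,-92.12,-104.63
DEHP,NA,2.8041,2.0000,3.3778,2.0000,NA,NA,NA,NA
DEHP-CH2CH3,DEHP,3.1331,2.3010,3.7670,2.3010,11.73,15.05,11.52,15.05
DEHP-CH=CH2,DEHP,3.0400,2.2218,3.6576,2.2218,8.41,11.09,8.28,11.09
DEHP-C6H5,DEHP,3.5918,2.6990,4.3170,2.6990,28.09,34.95,27.80,34.95
DEHP-OCH3,DEHP,1.9208,1.1871,2.3010,1.2676,-31.50,-40.65,-31.88,-36.62
DEHP-F,DEHP,2.3979,1.6383,2.9208,1.6990,-14.48,-18.09,-13.53,-15.05
DEHP-Br,DEHP,2.6990,1.8239,3.1898,1.8539,-3.75,-8.80,-5.57,-7.31
DEHP-NO2,DEHP,1.8239,1.1024,2.2218,1.1871,-34.96,-44.88,-34.22,-40.65
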