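compound,parent,log_koa,log_kow,half_life,reported_koa_rate,reported_kow_rate,reported_half_life_rate
DINP,NA,13.585,9.37,11,NA,NA,NA
DEHP,NA,12.557,8.39,11.7,NA,NA,NA
DINP-C6H5,DINP,12.378,7.23,14.2,-8.88,-22.84,29.1
DEHP-F,DEHP,10.980,7.84,12.8,-12.56,-6.56,9.4
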