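d2o_percent,adapted,light_intensity,division_number,percent_of_control,doubling_time_h,fold_retardation
0,FALSE,150,6.96,100,9.98,1
0,FALSE,200,7.44,100,9.05,1
0,FALSE,300,8.27,100,8.79,1
0,FALSE,400,9.35,100,7.98,1
70,FALSE,150,4.77,68.53,22.80,2.28
70,FALSE,200,4.54,61.00,13.35,1.48
70,FALSE,300,3.92,47.45,11.17,1.27
70,FALSE,400,4.76,50.85,9.28,1.16
99,FALSE,150,1.33,19.07,117.32,11.75
99,FALSE,200,1.38,18.49,86.27,9.53
99,FALSE,300,1.64,19.88,158.68,18.04
99,FALSE,400,1.14,12.23,145.78,18.28
99,TRUE,150,1.36,19.52,34.32,3.44
99,TRUE,200,1.12,15.05,46.13,5.10
99,TRUE,300,1.20,14.48,NA,NA
99,TRUE,400,1.43,15.31,NA,NA
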