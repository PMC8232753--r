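d2o_percent,adapted,light_intensity,mass_multiplication_factor,percent_of_control,mass_doubling_time_h,fold_retardation
0,FALSE,150,4.33,100,12.79,1
0,FALSE,200,5.65,100,11.65,1
0,FALSE,300,5.54,100,13.65,1
0,FALSE,400,5.74,100,10.60,1
70,FALSE,150,3.64,84.13,15.29,1.20
70,FALSE,200,3.42,60.52,13.75,1.18
70,FALSE,300,3.32,59.86,16.04,1.18
70,FALSE,400,4.03,70.27,13.24,1.25
99,FALSE,150,1.83,42.39,118.23,9.24
99,FALSE,200,1.29,22.73,142.92,12.26
99,FALSE,300,1.13,20.43,306.28,22.44
99,FALSE,400,1.05,18.23,309.10,29.17
99,TRUE,150,3.18,73.46,42.53,3.33
99,TRUE,200,2.78,49.20,47.62,4.09
99,TRUE,300,2.78,50.25,49.99,3.66
99,TRUE,400,2.11,36.68,49.09,4.63
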