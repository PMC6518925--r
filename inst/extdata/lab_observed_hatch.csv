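treatment,fert_date,mean_c,sd_c,atu50,atu50_sd,dpf50,dpf50_sd
A,2016-11-01,5.3,0.38,526,3.9,99,0.8
A,2016-11-04,5.3,0.24,526,9.2,100,1.8
A,2016-11-08,5.2,0.15,534,2.7,102,0.5
A,2016-11-11,5.2,0.15,521,1.5,99,0.3
B,2016-11-01,5.2,1.92,534,5.3,100,1.6
B,2016-11-04,5.2,1.90,531,3.0,103,0.9
B,2016-11-08,5.1,1.91,515,2.2,102,0.9
B,2016-11-11,5.2,1.94,501,2.2,101,0.7
C,2016-11-01,3.9,1.40,492,2.9,124,0.8
C,2016-11-04,3.9,1.33,485,6.9,125,2.0
C,2016-11-08,3.8,1.25,471,7.0,124,2.0
C,2016-11-11,3.7,1.24,476,3.8,127,1.1
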