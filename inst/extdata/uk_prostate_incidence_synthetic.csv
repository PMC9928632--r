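age_lo,age_hi,period_lo,period_hi,sex,site,rate
0,40,-Inf,Inf,M,prostate,0.000000000000000000000
40,45,-Inf,Inf,M,prostate,0.000050000000000000002
45,50,-Inf,Inf,M,prostate,0.000200000000000000010
50,55,-Inf,Inf,M,prostate,0.000550000000000000033
55,60,-Inf,Inf,M,prostate,0.001500000000000000031
60,65,-Inf,Inf,M,prostate,0.003500000000000000073
65,70,-Inf,Inf,M,prostate,0.006000000000000000125
70,75,-Inf,Inf,M,prostate,0.007499999999999999722
75,80,-Inf,Inf,M,prostate,0.008000000000000000167
80,85,-Inf,Inf,M,prostate,0.007499999999999999722
85,90,-Inf,Inf,M,prostate,0.007000000000000000146
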