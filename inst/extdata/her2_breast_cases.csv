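case,thickness_um,status,her2_mean,her2_cv,cep17_mean,cep17_cv,ratio_mean,ratio_cv
A,2,negative,2.2,0.092,2.0,0.195,1.1,0.079
A,4,negative,2.4,0.088,2.4,0.149,1.1,0.082
A,6,negative,3.0,0.076,2.8,0.102,1.1,0.075
B,2,negative,3.4,0.220,2.4,0.133,1.4,0.139
B,4,equivocal,4.4,0.202,3.6,0.259,1.2,0.052
B,6,equivocal,4.4,0.188,3.6,0.155,1.2,0.039
C,2,positive,7.9,0.340,2.3,0.372,3.5,0.033
C,4,positive,11.4,0.197,3.0,0.187,3.9,0.029
C,6,positive,12.6,0.132,3.8,0.123,3.3,0.028
D,2,equivocal,4.8,0.222,2.55,0.190,1.88,0.063
D,4,positive,5.8,0.171,2.65,0.179,2.19,0.074
D,6,positive,6.4,0.188,2.84,0.166,2.25,0.062
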