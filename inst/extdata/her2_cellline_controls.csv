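specimen,thickness_um,status,her2_mean,her2_cv,cep17_mean,cep17_cv,ratio_mean,ratio_cv
negative_control_293T,2,negative,2.2,0.087,2.2,0.184,1.0,0.129
negative_control_293T,3,negative,2.1,0.107,2.1,0.036,1.0,0.098
negative_control_293T,4,negative,2.4,0.196,2.4,0.264,1.0,0.096
negative_control_293T,5,negative,2.5,0.059,2.3,0.098,1.1,0.042
negative_control_293T,6,negative,2.5,0.165,2.4,0.250,1.1,0.097
positive_control_1_mix,2,positive,8.0,0.130,3.0,0.038,2.6,0.099
positive_control_1_mix,3,positive,8.2,0.196,2.6,0.037,3.1,0.164
positive_control_1_mix,4,positive,10.1,0.158,3.0,0.037,3.4,0.123
positive_control_1_mix,5,positive,11.7,0.103,3.3,0.131,3.5,0.129
positive_control_1_mix,6,positive,12.3,0.041,3.8,0.078,3.3,0.099
positive_control_2_SKBR3,2,positive,11.2,0.035,3.4,0.119,3.3,0.148
positive_control_2_SKBR3,3,positive,13.0,0.061,3.6,0.157,3.6,0.091
positive_control_2_SKBR3,4,positive,13.5,0.078,3.9,0.058,3.5,0.067
positive_control_2_SKBR3,5,positive,14.3,0.019,4.1,0.170,3.5,0.177
positive_control_2_SKBR3,6,positive,15.5,0.022,5.0,0.064,3.1,0.043
positive_control_2_SKBR3,8,positive,17.5,0.055,4.6,0.157,3.8,0.118
positive_control_2_SKBR3,10,positive,17.8,0.074,5.6,0.048,3.2,0.079
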