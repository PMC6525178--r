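specimen,thickness_um,status,met_mean,met_cv,cep7_mean,cep7_cv,ratio_mean,ratio_cv
lung_nsclc,2,negative,2.4,0.155,2.0,0.081,1.2,0.076
lung_nsclc,4,negative,3.1,0.131,2.6,0.143,1.2,0.015
lung_nsclc,6,negative,3.5,0.083,2.9,0.161,1.2,0.084
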