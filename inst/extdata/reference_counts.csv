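stratum,tp,fp,fn,tn,printed_sensitivity,printed_specificity,printed_ppv,printed_npv
all,18,7,0,42,1,0.857,0.72,1
lambda,7,2,0,20,1,0.909,0.778,1
kappa,11,5,0,22,1,0.815,0.688,1
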