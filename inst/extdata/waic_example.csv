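model,predictors,waic,weight_printed
1,intercept only,176083.7,0.00
2,individual-level effects,176051.5,0.01
3,environmental factors,176052.3,0.01
4,ecological risk,176042.9,0.81
5,gendered division of food production labour,176045.9,0.18
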