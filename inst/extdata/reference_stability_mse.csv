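measure,mse_reference_x100,mse_individual_x100,printed_relative,printed_ci_low,printed_ci_high
stratus_pct,6.0,14.5,2.4,1.6,3.3
densitas_pct,21.4,65.9,3.1,1.8,3.9
volpara_pct,4.2,10.0,2.4,1.8,3.0
nnvas_pct,12.0,19.7,1.6,1.3,2.3
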