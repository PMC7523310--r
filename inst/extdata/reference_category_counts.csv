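measure,horizon,cutpoint_display,tam_no_change,tam_intermediate,tam_decrease,ctrl_no_change,ctrl_intermediate,ctrl_decrease,printed_difference,printed_ci_low,printed_ci_high
visual_pct,T1_T0,-10.0,24,20,26,57,18,14,21,7,36
stratus_pct,T1_T0,-4.6,10,16,44,45,30,14,47,32,62
stratus_pct,T2_T0,-4.6,9,14,47,50,20,19,46,31,61
densitas_pct,T1_T0,-3.6,9,17,44,48,27,14,47,32,62
densitas_pct,T2_T0,-3.6,7,23,40,47,24,18,37,21,52
volpara_pct,T1_T0,-1.4,14,17,39,45,30,14,40,25,55
volpara_pct,T2_T0,-1.4,5,19,46,48,22,19,44,29,60
nnvas_pct,T1_T0,-4.4,8,24,38,36,39,14,39,23,54
nnvas_pct,T2_T0,-4.4,10,14,46,47,29,13,51,37,66
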