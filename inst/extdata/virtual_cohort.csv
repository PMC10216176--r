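case,response,ratio_bt,ratio_at,ratio_reduction_pct,mixing_score_change_pct,avg_neighbor_frequency_change_pct,gcross_auc_change_pct,shannon_entropy_change_pct
R1,R,2.86,0.43,84.96,64.03,67.25,34.71,310.13
R2,R,15.41,5.71,67.94,47.98,49.87,14.53,421.13
R3,R,3.67,0.57,84.46,63.35,64.92,30.81,300.76
R4,R,17.36,6.91,65.19,44.15,46.26,12.06,433.78
R5,R,3.45,0.49,85.79,64.69,67.38,34.67,347.19
NR1,NR,3.19,2.84,10.97,2.82,3.28,2.91,4.24
NR2,NR,16.92,13.46,20.45,0.78,1.71,0.81,2.31
NR3,NR,19.64,15.41,21.53,0.0,0.86,0.0,0.93
NR4,NR,6.94,5.81,16.28,2.68,2.87,1.71,3.92
NR5,NR,18.49,14.56,21.25,0.68,1.21,0.67,2.15
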