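allele,size_bp,approximate,sequenced,frequency_pct_printed,ps_printed,pi_printed,hyb_printed,total_printed
S_3-1,713,FALSE,TRUE,6.33,2,2,1,5
S_12,815,FALSE,TRUE,7.59,3,2,1,6
S_A,627,FALSE,TRUE,2.53,1,1,0,2
S_B,559,FALSE,TRUE,7.59,3,1,2,6
S_C,783,FALSE,TRUE,11.39,4,3,2,9
S_D,716,FALSE,TRUE,3.80,1,2,0,3
S_E,2100,TRUE,FALSE,1.27,1,0,0,1
S_G,980,TRUE,FALSE,1.27,0,1,0,1
S_H,1250,TRUE,FALSE,3.80,2,0,1,3
S_I,950,TRUE,FALSE,2.53,1,1,0,2
S_J,1013,FALSE,TRUE,2.53,1,1,0,2
S_K,1450,TRUE,TRUE,5.06,2,1,1,4
S_L,3000,TRUE,FALSE,2.53,1,1,0,2
S_M,1113,FALSE,TRUE,6.33,3,0,2,5
S_N,2500,TRUE,FALSE,1.27,1,0,0,1
S_O,490,TRUE,FALSE,1.27,1,0,0,1
S_P,1800,TRUE,TRUE,5.06,3,0,1,4
S_Q,610,TRUE,FALSE,1.27,1,0,0,1
S_T,2700,TRUE,FALSE,1.27,0,0,1,1
S_U,1400,TRUE,TRUE,3.80,1,2,0,3
S_V,1500,TRUE,FALSE,2.53,2,0,0,2
S_X,2600,TRUE,FALSE,2.53,1,0,1,2
S_Y,590,TRUE,FALSE,2.53,0,2,0,2
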