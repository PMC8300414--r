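period,n_milkings,n_cows,actual_yield,predicted_305
0-305,910,91,11462.84,11462.84
0-270,513,57,10236.95,11156.88
0-240,352,44,9602.265,11478.32
0-210,434,62,8303.107,11116.52
0-180,390,65,6779.897,10653.34
0-150,255,51,5639.378,10953.72
0-120,164,41,4622.313,9985.867
0-90,195,65,3356.83,9717.556
0-60,124,62,2138.613,5610.461
0-30,90,90,759.2602,7109.765
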