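max_day,a,b,c,area_window,predicted_305
30,15.0170,0.2425,-0.0013,833.222,18036.89
60,12.5080,0.3321,0.0026,1999.796,12258.44
90,11.0229,0.3903,0.0047,3243.969,10430.16
120,11.9886,0.3561,0.0038,4513.761,10997.52
150,12.1962,0.3491,0.0036,5771.006,11146.57
180,12.9338,0.3273,0.0032,6986.659,11309.45
210,13.3877,0.3152,0.0030,8172.895,11386.48
240,13.1579,0.3210,0.0031,9271.689,11333.51
270,13.4694,0.3132,0.0030,10337.96,11347.22
305,13.7833,0.3056,0.0029,11367.83,11367.83
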