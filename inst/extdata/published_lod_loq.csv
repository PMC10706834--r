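fraction_pct,measured_pct,measured_sd,rsd_pct,detection_rate_pct,deviation_pct
0.05,0,NA,NA,0,-100
0.1,0.15,0.12,81.28,75,51.71
0.2,0.36,0.08,22.78,100,81.89
0.5,0.37,0.03,8.85,100,-25.52
0.8,0.76,0.06,6.36,100,-4.52
1,1.15,0.05,4.46,100,15.28
5,5.51,0.31,5.71,100,10.10
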