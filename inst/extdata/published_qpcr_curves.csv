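species,slope,intercept,r_squared
rainbow_trout,-3.506,31.88,0.9916
atlantic_salmon,-3.231,31.57,0.9962
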