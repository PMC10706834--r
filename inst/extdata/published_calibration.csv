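trout_mass_fraction_pct,q_o,q_o_sd,q_s,q_s_sd,k_value
10,94.00,0.89,376.5,2.88,0.44
30,101.23,4.87,97.79,1.68,0.41
50,121.30,2.87,51.57,1.51,0.43
70,183.50,1.87,34.78,0.86,0.44
90,226.50,2.74,11.13,0.77,0.44
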