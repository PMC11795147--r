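mineral,rm_percent,biosolubility_yr,width_um_mean,width_um_sd,surface_area_um2_mean,surface_area_um2_sd
Chrysotile (Quebec),0.0014,0.3,0.37,0.0009,21.5,0.91
Amosite (South Africa),0.11,74,0.475,0.0086,14.48,0.86
Crocidolite (Australia and South Africa),0.52,66,0.31,0.0004,13.47,0.45
Anthophyllite (Russia),0.056,245,0.83,0.016,25.08,1.57
Libby amphiboles (Libby MT),0.03,49,0.66,0.009,21.97,0.91
Erionite (Karain Turkey),4.67,181,0.45,0.012,4.94,1.16
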