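mineral,avg_dcc,rm_percent_published,rm_percent_modeled
Chrysotile (Quebec),0.085,0.0014,0.0013
Amosite (South Africa),0.03,0.11,0.09
Crocidolite (Australia and South Africa),0.11,0.52,1.18
Anthophyllite (Russia),0.016,0.056,0.083
Libby amphiboles (Libby MT),0.021,0.03,0.025
Erionite (Karain Turkey),0.082,4.67,2.1
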