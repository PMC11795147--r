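mineral,relative_potency_rats,avg_dcc,biosolubility_yr,rm_percent_modeled,relative_potency_modeled
Crocidolite,1.22,0.089,66,0.748,1.20
Amosite,1.00,0.041,74,0.161,0.88
Tremolite,0.66,0.032,49,0.059,0.67
Anthophyllite,0.47,0.0139,245,0.062,0.68
Non-fibrous grunerite,0.1,0.0066,74,0.003,0.06
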