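mineral,density_g_cm3,biosolubility_yr,mineral_class
tremolite,3.0,49,amphibole_asbestiform_or_mixed
crocidolite,3.4,66,amphibole_asbestiform_or_mixed
riebeckite,3.4,66,other_nonserpentine
amosite,3.4,74,amphibole_asbestiform_or_mixed
grunerite,3.4,74,other_nonserpentine
anthophyllite,3.0,245,amphibole_asbestiform_or_mixed
chrysotile,2.55,0.3,serpentine
erionite,2.1,181,erionite
libby_amphibole,3.0,49,amphibole_asbestiform_or_mixed
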