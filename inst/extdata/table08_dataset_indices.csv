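dataset,group,habit_apriori,mineral_type,criteria_fraction,pearson_index,dcc
Udaipur India,testing,asbestiform,Tremolite,0.459,0.29,0.027
Lone Pine CA,testing,asbestiform,Tremolite,0.945,0.25,0.048
Yamaga Mine Japan,testing,asbestiform,Tremolite,0.818,0.23,0.040
Jamestown CA,testing,asbestiform,Tremolite,0.574,0.23,0.025
Korea,testing,asbestiform,Tremolite,0.914,0.13,0.057
HSE sample (1),testing,asbestiform,Tremolite,0.934,0.21,0.058
HSE sample (2),testing,asbestiform,Tremolite,0.937,0.18,0.044
Metsovo Greece,testing,asbestiform,Tremolite,0.887,0.28,0.068
Miners Bay Canada,testing,non-asbestiform,Tremolite,0.273,0.54,0.005
Gouverneur NY,testing,non-asbestiform,Tremolite,0.000,0.77,0.001
Sparta NJ,testing,non-asbestiform,Tremolite,0.150,0.33,0.004
Madagascar,testing,non-asbestiform,Tremolite,0.082,0.67,0.002
Shinness Scotland,testing,non-asbestiform,Tremolite,0.103,0.55,0.003
Dornie,testing,non-asbestiform,Tremolite,0.037,0.81,0.002
Swansea,testing,non-asbestiform,Tremolite,0.229,0.60,0.005
NIOSH cleavage fragments,testing,non-asbestiform,Tremolite,0.150,0.65,0.005
Eastern New York,validation,asbestiform,Tremolite,0.945,0.17,0.138
Falls Village CT,validation,non-asbestiform,Tremolite,0.278,0.55,0.007
Quebec Canada,validation,non-asbestiform,Tremolite,0.100,0.39,0.003
El Dorado Hills CA,unclassified,unclassified,Tremolite,0.114,0.67,0.003
Ala di Stura Italy,unclassified,unclassified,Tremolite,0.198,0.53,0.005
Brazil,unclassified,unclassified,Tremolite,0.125,0.35,0.003
Barstow CA,unclassified,unclassified,Tremolite,0.648,0.35,0.033
Libby MT amphiboles,unclassified,unclassified,Libby amphiboles,0.626,0.43,0.021
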