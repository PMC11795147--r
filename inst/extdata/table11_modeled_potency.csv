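dataset,group,habit_apriori,mineral_type,rm_empa_based,rm_dcc_based
Udaipur India,testing,asbestiform,Tremolite,0.018,0.039
Lone Pine CA,testing,asbestiform,Tremolite,0.085,0.144
Yamaga Mine Japan,testing,asbestiform,Tremolite,0.077,0.097
Jamestown CA,testing,asbestiform,Tremolite,0.059,0.034
Korea,testing,asbestiform,Tremolite,0.150,0.203
HSE sample (1),testing,asbestiform,Tremolite,0.284,0.209
HSE sample (2),testing,asbestiform,Tremolite,0.079,0.116
Metsovo Greece,testing,asbestiform,Tremolite,0.325,0.296
Miners Bay Canada,testing,non-asbestiform,Tremolite,-0.012,0.001
Gouverneur NY,testing,non-asbestiform,Tremolite,-0.012,0.000
Sparta NJ,testing,non-asbestiform,Tremolite,-0.012,0.001
Madagascar,testing,non-asbestiform,Tremolite,-0.012,0.000
Shinness Scotland,testing,non-asbestiform,Tremolite,-0.012,0.000
Dornie,testing,non-asbestiform,Tremolite,-0.012,0.000
Swansea,testing,non-asbestiform,Tremolite,-0.012,0.001
NIOSH cleavage fragments,testing,non-asbestiform,Tremolite,-0.007,0.001
Eastern New York,validation,asbestiform,Tremolite,0.701,1.362
Falls Village CT,validation,non-asbestiform,Tremolite,-0.012,0.002
Quebec Canada,validation,non-asbestiform,Tremolite,-0.012,0.000
El Dorado Hills CA,unclassified,unclassified,Tremolite,-0.012,0.000
Ala di Stura Italy,unclassified,unclassified,Tremolite,-0.012,0.001
Brazil,unclassified,unclassified,Tremolite,-0.012,0.000
Barstow CA,unclassified,unclassified,Tremolite,0.075,0.065
Libby MT amphiboles,unclassified,unclassified,Libby amphiboles,0.018,0.019
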