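dataset,group,habit_apriori,habit_aposteriori
Udaipur India,testing,asbestiform,asbestiform
Lone Pine CA,testing,asbestiform,asbestiform
Yamaga Mine Japan,testing,asbestiform,asbestiform
Jamestown CA,testing,asbestiform,asbestiform
Korea,testing,asbestiform,asbestiform
HSE sample (1),testing,asbestiform,asbestiform
HSE sample (2),testing,asbestiform,asbestiform
Metsovo Greece,testing,asbestiform,asbestiform
Miners Bay Canada,testing,non-asbestiform,non-asbestiform
Gouverneur NY,testing,non-asbestiform,non-asbestiform
Sparta NJ,testing,non-asbestiform,non-asbestiform
Madagascar,testing,non-asbestiform,non-asbestiform
Shinness Scotland,testing,non-asbestiform,non-asbestiform
Dornie,testing,non-asbestiform,non-asbestiform
Swansea,testing,non-asbestiform,non-asbestiform
NIOSH cleavage fragments,testing,non-asbestiform,non-asbestiform
Eastern New York,validation,asbestiform,asbestiform
Falls Village CT,validation,non-asbestiform,non-asbestiform
Quebec Canada,validation,non-asbestiform,non-asbestiform
El Dorado Hills CA,unclassified,unclassified,non-asbestiform
Ala di Stura Italy,unclassified,unclassified,non-asbestiform
Brazil,unclassified,unclassified,non-asbestiform
Barstow CA,unclassified,unclassified,asbestiform
Libby MT amphiboles,unclassified,unclassified,asbestiform
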