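dataset,group,habit_apriori,mineral_type,mean_length,sd_length,mean_width,sd_width,mean_ar,sd_ar,mean_ad,sd_ad,empa_fraction,sd_empa,mean_sa,sd_sa
Udaipur India,testing,asbestiform,Tremolite,9.30,1.18,0.77,0.09,30.53,4.26,3.67,0.40,0.027,0.033,18.15,5.03
Lone Pine CA,testing,asbestiform,Tremolite,11.60,0.25,0.34,0.02,43.48,0.89,1.74,0.08,0.088,0.007,12.02,1.05
Yamaga Mine Japan,testing,asbestiform,Tremolite,13.88,0.50,0.51,0.04,40.84,1.79,2.56,0.17,0.081,0.014,21.27,2.12
Jamestown CA,testing,asbestiform,Tremolite,8.70,0.49,0.70,0.04,24.08,1.76,3.30,0.16,0.065,0.013,17.13,2.08
Korea,testing,asbestiform,Tremolite,11.40,0.51,0.35,0.04,48.31,1.84,1.77,0.17,0.147,0.014,11.93,2.18
HSE sample (1),testing,asbestiform,Tremolite,9.74,0.49,0.30,0.04,46.31,1.78,1.54,0.17,0.269,0.014,9.25,2.10
HSE sample (2),testing,asbestiform,Tremolite,11.33,0.50,0.35,0.04,39.74,1.80,1.78,0.17,0.083,0.014,12.33,2.13
Metsovo Greece,testing,asbestiform,Tremolite,8.65,0.91,0.32,0.07,52.84,3.29,1.56,0.31,0.306,0.025,7.62,3.89
Miners Bay Canada,testing,non-asbestiform,Tremolite,8.42,2.17,0.84,0.17,10.59,7.80,4.08,0.73,0.000,0.060,28.09,9.23
Gouverneur NY,testing,non-asbestiform,Tremolite,7.68,1.15,1.62,0.09,5.01,4.14,7.04,0.39,0.000,0.032,44.92,4.90
Sparta NJ,testing,non-asbestiform,Tremolite,7.79,0.51,1.07,0.04,8.78,1.83,4.95,0.17,0.000,0.014,28.67,2.16
Madagascar,testing,non-asbestiform,Tremolite,8.06,0.25,1.31,0.02,7.06,0.90,5.83,0.08,0.000,0.007,36.80,1.07
Shinness Scotland,testing,non-asbestiform,Tremolite,7.71,0.36,1.32,0.03,7.23,1.31,5.87,0.12,0.000,0.010,36.52,1.55
Dornie,testing,non-asbestiform,Tremolite,7.39,0.53,1.56,0.04,5.31,1.89,6.71,0.18,0.000,0.015,40.43,2.24
Swansea,testing,non-asbestiform,Tremolite,10.16,0.50,1.15,0.04,11.73,1.79,5.29,0.17,0.000,0.014,38.09,2.11
NIOSH cleavage fragments,testing,non-asbestiform,Tremolite,9.00,0.47,1.40,0.04,8.75,1.70,6.28,0.16,0.004,0.013,44.85,2.01
Eastern New York,validation,asbestiform,Tremolite,13.68,0.75,0.23,0.06,120.56,2.71,1.15,0.25,0.648,0.021,10.87,3.21
Falls Village CT,validation,non-asbestiform,Tremolite,7.55,1.69,1.10,0.13,10.30,6.10,4.95,0.57,0.000,0.047,30.53,7.22
Quebec Canada,validation,non-asbestiform,Tremolite,7.47,2.27,0.96,0.18,8.36,8.19,4.49,0.76,0.000,0.063,23.14,9.68
El Dorado Hills CA,unclassified,unclassified,Tremolite,9.38,0.19,1.44,0.01,8.02,0.67,6.48,0.06,0.000,0.005,38.85,0.79
Ala di Stura Italy,unclassified,unclassified,Tremolite,9.24,0.52,1.22,0.04,10.24,1.87,5.51,0.17,0.000,0.014,31.33,2.21
Brazil,unclassified,unclassified,Tremolite,7.45,0.29,1.31,0.02,7.31,1.04,5.77,0.10,0.000,0.008,33.81,1.23
Barstow CA,unclassified,unclassified,Tremolite,11.64,0.18,0.69,0.01,32.26,0.65,3.28,0.06,0.080,0.005,25.08,0.77
Libby MT amphiboles,unclassified,unclassified,Libby amphiboles,10.72,0.30,0.70,0.01,22.55,1.28,3.43,0.04,0.028,0.004,23.08,0.86
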