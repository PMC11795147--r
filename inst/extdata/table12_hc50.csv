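sample,dataset,hc50_mg_ml,hc50_fibers_1e9_ml
Tremolite Udaipur India,Udaipur India,2.81,0.41
Tremolite Jamestown CA,Jamestown CA,1.14,0.17
Tremolite Korea,Korea,1.38,0.51
Tremolite Metsovo Greece,Metsovo Greece,3.06,1.7
Tremolite Swansea,Swansea,2.53,0.09
Libby MT amphiboles,Libby MT amphiboles,2.07,0.22
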