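host,Cotesia_sp,Aleiodes_sp,Ichneumon_A,Pteromalus_B
Gynaephora_groenlandica,12,3,0,0
Gynaephora_rossii,4,6,1,0
Sympistis_zetterstedtii,0,0,7,2
Eurois_occulta,0,0,3,0
Syngrapha_interrogationis,0,0,0,0
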