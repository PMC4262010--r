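host,parasitoid,weight
Gynaephora_groenlandica,Cotesia_sp,12
Gynaephora_groenlandica,Aleiodes_sp,3
Gynaephora_rossii,Cotesia_sp,4
Gynaephora_rossii,Aleiodes_sp,6
Gynaephora_rossii,Ichneumon_A,1
Sympistis_zetterstedtii,Ichneumon_A,7
Sympistis_zetterstedtii,Pteromalus_B,2
Eurois_occulta,Ichneumon_A,3
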