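host,species,genus,family,order
Gynaephora_groenlandica,Gynaephora_groenlandica,Gynaephora,Erebidae,Lepidoptera
Gynaephora_rossii,Gynaephora_rossii,Gynaephora,Erebidae,Lepidoptera
Sympistis_zetterstedtii,Sympistis_zetterstedtii,Sympistis,Noctuidae,Lepidoptera
Eurois_occulta,Eurois_occulta,Eurois,Noctuidae,Lepidoptera
Syngrapha_interrogationis,Syngrapha_interrogationis,Syngrapha,Noctuidae,Lepidoptera
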