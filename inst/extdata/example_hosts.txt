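Gynaephora_groenlandica
Gynaephora_rossii
Sympistis_zetterstedtii
Eurois_occulta
Syngrapha_interrogationis
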