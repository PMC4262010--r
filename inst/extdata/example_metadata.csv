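study_id,network_id,latitude,guild
zackenberg,arctic1,74.5,leaf chewers
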