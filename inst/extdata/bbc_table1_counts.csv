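group,n,n_owo
early-OWO,388,252
late-OWO,254,170
NW-A,186,0
NW-B,118,3
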