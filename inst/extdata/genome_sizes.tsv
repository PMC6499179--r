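species	two_c_pg
Cercis	0.751
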