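CpG,Weight
Intercept,40.5
cg00000001,10
cg00000002,-3.25
cg00000003,0.5
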