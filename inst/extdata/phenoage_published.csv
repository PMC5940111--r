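constant,value
weight.albumin,-0.0336
weight.creatinine,0.0095
weight.glucose,0.1953
weight.crp,0.0954
weight.lymphocyte_pct,-0.0120
weight.mcv,0.0268
weight.rdw,0.3306
weight.alp,0.0019
weight.wbc,0.0554
weight.age,0.0804
intercept,-19.9067
gamma,0.0076927
horizon,120
ao.offset,141.50225
ao.scale,0.090165
ao.const,0.00553
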