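parent,dimension,children,max_cv_before,weighted_max_cv_after
"Milk, cow, pasteurized, full fat, chocolate",sweetener,"Milk, cow, pasteurized, full fat, chocolate, with sweeteners | Milk, cow, pasteurized, full fat, chocolate, with sugar",0.5493746444822513,0.04772727272727272
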