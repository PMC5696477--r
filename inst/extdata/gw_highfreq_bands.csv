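conformer,mode_label,theory,experiment
gw2,NH_PB,3342,3337
gw2,NH_ind,3504,3520
gw3,NH_PB,3382,3396
gw3,NH_ind,3515,3522
gw3,OH_carb,3610,3583
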