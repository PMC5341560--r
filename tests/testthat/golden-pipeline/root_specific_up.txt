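LR00119|c3|LR00123
LR00366|c1|LR00366
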