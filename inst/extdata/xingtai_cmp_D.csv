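code,D_1,D_2,D_3
D_1,1,1,2
D_2,1,1,1
D_3,0,1,1
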