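code,S_1,S_2,S_3,S_4,S_5,S_6,S_7
S_1,1,0,0,0,0,0,0
S_2,2,1,2,0,0,1,1
S_3,2,0,1,1,1,0,0
S_4,2,2,1,1,1,2,2
S_5,2,2,1,1,1,1,2
S_6,2,1,2,0,1,1,1
S_7,2,1,2,0,0,1,1
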