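code,R_1,R_2,R_3
R_1,1,0,0
R_2,2,1,1
R_3,2,1,1
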