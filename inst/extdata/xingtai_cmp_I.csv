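code,I_1,I_2,I_3
I_1,1,0,0
I_2,2,1,0
I_3,2,2,1
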