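code,P_1,P_2,P_3,P_4,P_5,P_6,P_7,P_8
P_1,1,0,0,0,0,1,0,0
P_2,2,1,2,0,0,0,1,2
P_3,2,0,1,0,0,1,0,0
P_4,2,2,2,1,1,2,2,2
P_5,2,2,2,1,1,2,2,2
P_6,1,2,1,0,0,1,2,1
P_7,2,1,2,0,0,0,1,1
P_8,2,0,2,0,0,1,1,1
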