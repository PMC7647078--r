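code,D,P,S,I,R
D,1,0,0,0,0
P,2,1,2,2,2
S,2,0,1,0,1
I,2,0,2,1,2
R,2,0,1,0,1
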