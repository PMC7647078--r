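code,weight
D_1,0.0436
D_2,0.0388
D_3,0.0236
P_1,0.0351
P_2,0.0332
P_3,0.0503
P_4,0.0371
P_5,0.0659
P_6,0.0246
P_7,0.0337
P_8,0.0171
S_1,0.0591
S_2,0.0361
S_3,0.0415
S_4,0.0516
S_5,0.0505
S_6,0.0623
S_7,0.0365
I_1,0.0483
I_2,0.0551
I_3,0.0545
R_1,0.0273
R_2,0.0361
R_3,0.0381
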