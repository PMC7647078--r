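code,name,layer,polarity,units
D_1,Per capita GDP,D,+,yuan/person
D_2,Population density,D,-,person/km2
D_3,Natural population growth rate,D,-,%
P_1,Economic density,P,+,yuan/km2
P_2,Proportion of primary industry,P,-,%
P_3,Proportion of secondary industry,P,-,%
P_4,Fertilizer usage,P,-,t/hm2
P_5,Pesticide usage,P,-,kg/hm2
P_6,Urbanization level,P,-,%
P_7,Per capita cultivated land,P,+,hm2/person
P_8,Per capita water resources,P,+,m3/person
S_1,Employment rate,S,+,%
S_2,Output value of GDP per unit cultivated land,S,+,yuan/hm2
S_3,Proportion of grassland area,S,+,%
S_4,Proportion of forest land area,S,+,%
S_5,Forest coverage,S,+,%
S_6,Land reclamation rate,S,-,%
S_7,Grain output per unit cultivated land,S,+,kg/hm2
I_1,Proportion of tertiary industry,I,+,%
I_2,Degree of machine cultivation,I,+,%
I_3,Investment in environmental pollution treatment,I,+,%
R_1,Soil and water coordination degree,R,+,%
R_2,Level of farming mechanization,R,+,kw/hm2
R_3,Agricultural power intensity,R,+,kwh/hm2
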