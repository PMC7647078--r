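year,T,D,P,S,I,R
2006,0.28,0.05,0.09,0.06,0.04,0.03
2007,0.37,0.05,0.10,0.10,0.04,0.08
2008,0.36,0.04,0.08,0.10,0.09,0.05
2009,0.35,0.04,0.18,0.06,0.05,0.02
2010,0.35,0.03,0.16,0.06,0.06,0.04
2011,0.37,0.04,0.16,0.08,0.04,0.05
2012,0.34,0.04,0.15,0.07,0.01,0.07
2013,0.50,0.04,0.22,0.12,0.04,0.08
2014,0.52,0.04,0.15,0.08,0.15,0.09
2015,0.48,0.05,0.16,0.10,0.08,0.10
2016,0.45,0.05,0.17,0.10,0.07,0.06
2017,0.66,0.06,0.22,0.15,0.15,0.07
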