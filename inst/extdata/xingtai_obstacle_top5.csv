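year,rank,code,obstacle_pct
2006,1,I_3,10.38
2006,2,P_5,9.62
2006,3,P_4,7.12
2006,4,R_3,6.76
2006,5,I_2,6.38
2007,1,P_5,11.27
2007,2,I_3,11.02
2007,3,I_2,9.80
2007,4,P_4,7.49
2007,5,I_1,6.09
2008,1,P_5,12.16
2008,2,P_4,9.91
2008,3,I_2,7.02
2008,4,R_3,6.96
2008,5,I_3,6.14
2009,1,P_5,9.82
2009,2,I_3,9.70
2009,3,I_2,9.19
2009,4,R_3,6.88
2009,5,S_6,6.32
2010,1,I_3,11.48
2010,2,P_5,10.61
2010,3,I_2,6.34
2010,4,S_6,6.32
2010,5,R_3,5.73
2011,1,I_3,15.41
2011,2,P_5,11.31
2011,3,S_6,6.62
2011,4,I_2,6.04
2011,5,P_3,5.26
2012,1,I_3,14.89
2012,2,P_5,11.36
2012,3,I_2,9.86
2012,4,S_6,6.22
2012,5,I_1,4.67
2013,1,I_3,18.12
2013,2,I_2,10.59
2013,3,S_6,7.93
2013,4,P_4,5.56
2013,5,I_1,5.39
2014,1,P_5,12.81
2014,2,P_4,9.01
2014,3,S_6,7.87
2014,4,I_2,7.65
2014,5,S_3,5.73
2015,1,P_5,11.56
2015,2,I_3,11.36
2015,3,I_2,10.98
2015,4,P_4,8.43
2015,5,S_6,7.37
2016,1,I_3,18.04
2016,2,P_5,10.73
2016,3,R_2,8.68
2016,4,S_6,6.90
2016,5,P_7,6.05
2017,1,I_3,15.57
2017,2,R_2,12.77
2017,3,P_5,11.59
2017,4,S_6,10.58
2017,5,P_7,10.5
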