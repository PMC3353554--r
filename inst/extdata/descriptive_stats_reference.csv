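year,date,mean,variance,minimum,maximum,n,upper_threshold,lower_threshold
2004,2004-04-23,1.04,0.32,0.00,1.75,7,2.74,-0.67
2004,2004-04-30,1.54,0.40,0.50,2.25,7,3.44,-0.37
2004,2004-05-07,2.11,0.33,1.25,2.75,7,3.83,0.38
2004,2004-05-14,2.54,0.24,1.75,3.00,7,4.00,1.07
2004,2004-05-21,3.04,0.26,2.25,3.50,7,4.56,1.51
2004,2004-05-28,3.68,0.31,2.75,4.00,7,5.34,2.02
2005,2005-04-22,0.42,0.14,0.00,1.00,6,1.55,-0.71
2005,2005-04-29,1.18,0.26,0.50,2.00,7,2.72,-0.37
2005,2005-05-06,2.11,0.48,1.50,3.50,7,4.18,0.04
2005,2005-05-13,2.82,0.41,2.25,4.00,7,4.74,0.90
2005,2005-05-20,3.25,0.20,2.75,4.00,7,4.59,1.91
2006,2006-04-13,0.64,0.14,0.00,1.25,7,1.78,-0.49
2006,2006-04-20,1.14,0.18,0.75,2.00,7,2.43,-0.15
2006,2006-04-27,1.57,0.16,1.00,2.25,7,2.77,0.37
2006,2006-05-04,2.18,0.16,1.50,2.75,7,3.38,0.98
2006,2006-05-11,2.61,0.16,2.00,3.25,7,3.82,1.39
2006,2006-05-18,3.18,0.20,2.50,3.75,7,4.53,1.83
2006,2006-05-25,3.79,0.15,3.00,4.00,7,4.97,2.61
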