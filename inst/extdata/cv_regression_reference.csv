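year,date,regression_coefficient
2004,2004-04-23,0.93
2004,2004-04-30,1.14
2004,2004-05-07,1.12
2004,2004-05-14,1.12
2004,2004-05-21,0.99
2004,2004-05-28,0.78
2005,2005-04-22,0.73
2005,2005-04-29,0.99
2005,2005-05-06,0.41
2005,2005-05-13,0.48
2005,2005-05-20,0.47
2006,2006-04-13,0.59
2006,2006-04-20,0.47
2006,2006-04-27,0.41
2006,2006-05-04,0.38
2006,2006-05-11,0.80
2006,2006-05-18,0.92
2006,2006-05-25,1.12
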