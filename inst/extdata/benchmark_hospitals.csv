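hospital,n_admissions,observed,expected,ramr_printed,ramr_ci_low,ramr_ci_high
1,737,39,89.65,4.54,3.32,6.21
2,167,5,10.58,4.82,2.01,11.58
3,232,9,18.99,4.83,2.52,9.29
4,209,10,20.10,5.07,2.73,9.43
5,2158,71,123.56,5.86,4.64,7.40
124,289,42,27.43,15.62,11.54,21.13
125,24,5,3.21,15.90,6.62,38.19
126,21,4,2.50,16.31,6.12,43.44
127,348,63,37.45,17.16,13.40,21.96
128,97,19,9.97,19.44,12.40,30.48
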