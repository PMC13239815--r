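lc,error_m
3,500
2,1000
1,1200
0,4200
A,6200
B,10300
Z,30000
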