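phenotype,n,deaths_24h,deaths_72h,deaths_30d,transfused_4h,eot
A,33,1,1,10,15,16
B,17,0,0,5,8,10
C,24,0,0,4,13,13
D,21,11,12,16,19,19
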