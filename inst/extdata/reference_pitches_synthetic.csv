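interval_id,length_nm,U_k2_nm
1,10000,30
2,10000,30
3,10000,30
4,10000,30
5,10000,30
6,10000,30
7,10000,30
8,10000,30
9,10000,30
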