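true,0,0.05,0.1,0.3,0.6,0.9,1
0,1311,1,2,0,0,0,0
0.05,11,35,0,0,0,0,0
0.1,0,0,70,0,0,0,0
0.3,0,0,0,57,0,0,0
0.6,1,0,0,0,62,0,0
0.9,0,0,0,0,0,61,0
1,0,0,0,0,0,0,59
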