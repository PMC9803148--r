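true,Zero,Low,Medium,High
Zero,1898,15,0,0
Low,31,264,1,0
Medium,6,18,62,1
High,2,0,2,116
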