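true,Low,Medium,High
Low,2050,18,1
Medium,21,198,7
High,3,2,115
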