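year,l1_count,l2_count
1975,100,20000
1980,6525,326521
1997,241709,599438
2007,470690,612992
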