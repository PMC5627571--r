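0100000000
0000001000
0000001000
0000110000
0000110000
1111000111
1111000111
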