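pattern,output
0011,0
1100,0
0101,1
1010,1
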