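pattern,output
00,0
01,1
10,1
11,0
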