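pattern,output
000111,0
111000,0
001011,1
110100,1
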