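source_id,time_ms
1,10
3,10
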