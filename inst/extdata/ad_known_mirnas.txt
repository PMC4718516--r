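miR-153
miR-17
miR-20a
miR-29b-1
miR-9
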