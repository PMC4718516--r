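miR-101-1
miR-107
miR-124-1
miR-135a1
miR-142
miR-146a
miR-155
miR-15a
miR-181a1
miR-184
miR-19a
miR-221
miR-298
miR-302a
miR-328
miR-520B
miR-7-1
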