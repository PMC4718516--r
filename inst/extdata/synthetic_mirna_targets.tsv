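source	target	type	directed
miR-153	APP	miRNA regulation	TRUE
miR-17	APP	miRNA regulation	TRUE
miR-20a	APP	miRNA regulation	TRUE
miR-9	APP	miRNA regulation	TRUE
miR-101-1	APP	miRNA regulation	TRUE
miR-29b-1	BACE1	miRNA regulation	TRUE
miR-107	BACE1	miRNA regulation	TRUE
miR-124-1	BACE1	miRNA regulation	TRUE
miR-135a1	BACE1	miRNA regulation	TRUE
miR-142	BACE1	miRNA regulation	TRUE
miR-146a	BACE1	miRNA regulation	TRUE
miR-155	BACE1	miRNA regulation	TRUE
miR-15a	BACE1	miRNA regulation	TRUE
miR-184	BACE1	miRNA regulation	TRUE
miR-181a1	CD4	miRNA regulation	TRUE
miR-19a	CD4	miRNA regulation	TRUE
miR-221	CD4	miRNA regulation	TRUE
miR-298	CD4	miRNA regulation	TRUE
miR-302a	CD4	miRNA regulation	TRUE
miR-328	IL8	miRNA regulation	TRUE
miR-520B	IL8	miRNA regulation	TRUE
miR-7-1	IL8	miRNA regulation	TRUE
miR-9	PSEN1	miRNA regulation	TRUE
miR-181a1	DCN	miRNA regulation	TRUE
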