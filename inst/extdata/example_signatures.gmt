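SIG_A	example	TP53	MYC	CDKN1A
SIG_B	example	VEGFA	IL1A	PTGS2	MIF
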