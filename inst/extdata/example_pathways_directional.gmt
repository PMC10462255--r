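P38	example directional set	ARG2|up	CD55|up	CYP4F3|up	FST|up	GCLC|up	IL1A|up	MIF|up	PLA2G4A|up	PTGS2|up	S100A12|up	SLC6A2|up	VEGFA|up
CTNNB1	example directional set	AXIN2|up	CCND1|up	MYC|up	LEF1|up	CDH1|down
HIF1A	example directional set	VEGFA|up	SLC2A1|up	LDHA|up	PGK1|up	EPO|up	BNIP3|up
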