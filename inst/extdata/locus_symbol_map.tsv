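verbatim	canonical	note
TIMMCD1	TIMMDC1	transposed letters in printed table
ZFPl36F1	ZFP36L1	garbled symbol in printed table
TNFSF1	TNFSF11	13q14 region gene; printed symbol truncated
ATP882	ATP8B2	digit/letter confusion in printed table
PRRL5	PRR5L	transposed letters in printed table
PRM1-RM12	PRM1-RMI2	RMI2 printed as RM12
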