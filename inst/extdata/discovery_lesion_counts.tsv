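direction	gene	total	biallelic_or_multiple	subclonal
loss	VPREB1	84	18	5
loss	CDKN2A/B	72	28	5
loss	ETV6	68	4	6
loss	PAX5	43	0	6
loss	IKZF1	34	1	5
loss	MLLT3	28	5	4
loss	PAR1	20	0	2
loss	TBL1XR1	19	1	0
loss	BTG1	17	0	0
loss	RB1	15	6	0
loss	BTLA/CD200	15	0	0
loss	CASP8AP2	15	0	2
loss	TP53	10	1	1
loss	CTCF	9	0	1
loss	NR3C1	8	0	2
loss	EBF1	5	0	0
loss	ERG	4	0	0
loss	LEF1	4	0	0
loss	PTEN	4	0	2
loss	NF1	3	0	0
loss	NR3C2	3	0	0
loss	EZH2	2	0	0
loss	SUZ12	2	0	0
loss	IKZF2	1	1	0
loss	NOTCH1	1	0	0
loss	PHF6	1	0	0
loss	PTPN2	1	0	0
gain	RUNX1	23	11	1
gain	PHF6	11	4	0
gain	ABL1	6	1	0
gain	MYB	1	0	0
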