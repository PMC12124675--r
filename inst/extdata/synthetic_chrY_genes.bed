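chrY	2780000	2790000	SRY	protein_coding
chrY	2900000	2950000	ZFY	protein_coding
chrY	4900000	5700000	PCDH11Y	protein_coding
chrY	6860000	6890000	AMELY	protein_coding
chrY	6910000	7090000	TBL1Y	protein_coding
chrY	9300000	9320000	TSPY1	protein_coding
chrY	9600000	9620000	TTTY22	RNA
chrY	9700000	9720000	ENSG00000228379	RNA
chrY	12700000	12860000	USP9Y	protein_coding
chrY	12870000	12890000	TTTY15	RNA
chrY	12900000	12920000	DDX3Y	protein_coding
chrY	13230000	13480000	UTY	protein_coding
chrY	14500000	14800000	NLGN4Y	protein_coding
chrY	15000000	15020000	TMSB4Y	protein_coding
chrY	16000000	16020000	ENSG00000236951	RNA
chrY	16100000	16120000	ENSG00000291034	RNA
chrY	16200000	16205000	RNU6-1314P	RNA
chrY	17000000	17020000	TTTY5	RNA
chrY	18500000	18540000	HSFY1	protein_coding
chrY	19000000	19010000	TTTY13	RNA
chrY	19700000	19750000	KDM5D	protein_coding
chrY	20750000	20780000	RPS4Y2	protein_coding
chrY	20900000	20920000	EIF1AY	protein_coding
chrY	21440000	21460000	RBMY2FP	RNA
chrY	21500000	21540000	RBMY1A1	protein_coding
chrY	21560000	21600000	RBMY1E	protein_coding
chrY	21620000	21660000	RBMY1F	protein_coding
chrY	21680000	21720000	RBMY1J	protein_coding
chrY	22100000	22130000	PRY	protein_coding
chrY	22160000	22190000	PRY2	protein_coding
chrY	22400000	22440000	BPY2	protein_coding
chrY	23000000	23040000	BPY2B	protein_coding
chrY	23300000	23370000	DAZ1	protein_coding
chrY	23400000	23470000	DAZ2	protein_coding
chrY	23600000	23670000	DAZ3	protein_coding
chrY	23700000	23770000	DAZ4	protein_coding
chrY	23900000	23930000	CDY1B	protein_coding
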