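chrY	2700000	3700000
chrY	6000000	7500000
chrY	12000000	14500000
chrY	17500000	18400000
chrY	19600000	20950000
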