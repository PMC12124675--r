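chrY	100000	2400000
chrY	2600000	10200000
chrY	10500000	20000000
chrY	20500000	24500000
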