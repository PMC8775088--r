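CHROM	POS	ALLELE	POP
1	700	C	POPA
1	1000	T	POPB
1	100	A	POPA
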