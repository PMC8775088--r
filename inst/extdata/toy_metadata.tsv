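sample	pop	super_pop	center
S1	POPA	EUR	CTRX
S2	POPA	EUR	CTRX
S3	POPA	EUR	CTRY
S4	POPB	EUR	CTRX
S5	POPB	EUR	CTRY
S6	POPB	EUR	CTRY
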