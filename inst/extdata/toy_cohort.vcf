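##fileformat=VCFv4.2
##source=batchfst-toy-fixture-synthetic
##INFO=<ID=AC,Number=1,Type=Integer,Description="Alternate allele count across samples">
##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">
##INFO=<ID=P1,Number=1,Type=String,Description="Predictor 1 label">
##INFO=<ID=P2,Number=1,Type=String,Description="Predictor 2 label">
##INFO=<ID=P3,Number=1,Type=String,Description="Predictor 3 label">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3	S4	S5	S6
1	100	.	A	G	.	PASS	AC=1;AA=A	GT	0/1	0/0	0/0	0/0	0/0	0/0
1	200	.	C	T	.	PASS	AC=1;AA=.	GT	0/0	0/1	0/0	0/0	0/0	0/0
1	300	.	G	A	.	PASS	AC=1;AA=-	GT	0/0	0/0	0/1	0/0	0/0	0/0
1	400	.	T	C	.	PASS	AC=1;AA=N	GT	0/0	0/0	0/0	0/1	0/0	0/0
1	500	.	A	G	.	PASS	AC=1;AA=G	GT	0/0	0/0	0/0	0/0	0/1	0/0
1	600	.	A	C	.	PASS	AC=1;AA=T	GT	0/0	0/0	0/0	0/0	0/0	0/1
1	700	.	G	C	.	PASS	AC=2;AA=G;P1=D;P2=D;P3=D	GT	0/1	0/0	0/0	0/1	0/0	0/0
1	800	.	C	G	.	PASS	AC=3;AA=C;P1=D;P2=D;P3=D	GT	0/0	1/1	0/1	0/0	0/0	0/0
1	900	.	T	A	.	PASS	AC=2;AA=T;P1=D;P2=D;P3=B	GT	0/0	0/0	0/1	0/0	0/1	0/0
1	1000	.	A	T	.	PASS	AC=4;AA=A;P1=B;P2=B;P3=B	GT	0/1	0/0	0/0	0/0	0/1	1/1
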