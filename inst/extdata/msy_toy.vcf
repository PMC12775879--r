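##fileformat=VCFv4.2
##contig=<ID=Y>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	M1	M2	M3	M4	M5	F1	F2	F3
Y	100	.	A	G	.	PASS	.	GT	0	1	0	1	0	0/1	0/0	1/1
Y	200	.	C	T	.	PASS	.	GT	.	0	1	0	0	0/0	0/1	1/1
Y	300	.	G	A	.	PASS	.	GT	0	0	0	0	0	0/1	1/1	0/0
Y	400	.	T	C	.	PASS	.	GT	1	1	0	1	0	0/0	0/1	1/1
Y	500	.	A	C	.	PASS	.	GT	0/1	1	0	0	1	0/0	0/0	0/1
Y	600	.	G	T	.	PASS	.	GT	0	0	1	0	0	1/1	0/1	0/0
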