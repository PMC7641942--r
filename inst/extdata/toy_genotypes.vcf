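##fileformat=VCFv4.2
##source=earlyt1d toy fixture (synthetic data, hand-tabulated companion in toy_dosages_expected.csv)
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
1	100	rsA	G	A	.	PASS	.	GT	0/1	1/1	0/0
1	200	rsB	C	T	.	PASS	.	GT	0/0	0/1	./.
2	300	rsC	G	A	.	PASS	.	GT	1/1	0/1	0/0
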