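snp_id	effect_allele	other_allele	odds_ratio
snp01	A	G	6.8
snp02	C	T	3.9
snp03	G	A	2.3
snp04	T	C	1.9
snp05	A	G	1.8
snp06	C	T	1.7
snp07	G	A	1.65
snp08	T	C	1.6
snp09	A	G	1.55
snp10	C	T	1.5
snp11	G	A	1.45
snp12	T	C	1.4
snp13	A	G	1.38
snp14	C	T	1.35
snp15	G	A	1.32
snp16	T	C	1.3
snp17	A	G	1.28
snp18	C	T	1.25
snp19	G	A	1.23
snp20	T	C	1.2
snp21	A	G	1.19
snp22	C	T	1.17
snp23	G	A	1.15
snp24	T	C	1.14
snp25	A	G	1.12
snp26	C	T	1.11
snp27	G	A	1.1
snp28	T	C	1.08
snp29	A	G	1.06
snp30	C	T	1.05
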