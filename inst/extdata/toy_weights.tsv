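snp_id	effect_allele	other_allele	odds_ratio
rsA	A	G	2.0
rsB	C	T	1.5
rsC	G	A	0.8
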