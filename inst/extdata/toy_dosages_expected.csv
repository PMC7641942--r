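individual_id,rsA,rsB,rsC
S1,1,2,0
S2,2,1,1
S3,0,NA,2
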