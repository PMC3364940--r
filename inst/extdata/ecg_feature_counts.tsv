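genotype	two_or_more_features	one_or_no_feature	total
wt	8	23	31
Ts65Dn	27	2	29
Ts65Dn/Ms5Yah	4	8	12
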