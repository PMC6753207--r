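target_rsid	proxy_rsid	r2	target_allele	proxy_allele
rs000003	rs900001	0.96	A	A
rs000003	rs900001	0.96	G	G
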