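# Toy gene-list collection: two ranked screens, one unranked pathway set
screenA	rnai	RANKED	TP53	EGFR	KRAS	MYC	BRCA1
screenB	crispr	RANKED	EGFR	TP53	PIK3CA	KRAS
pathway	literature	UNRANKED	KRAS	TP53	STK11
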