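node_a	node_b	direction	count_change	fa_contra	fa_ipsi	fa_sig	md_contra	md_ipsi	md_sig
SFG	IFGtriang	increased	18.18	0.38	0.33	decreased	0.88	1.10	increased
SFG	SMA	increased	11.41	0.39	0.33	decreased	0.94	1.13	increased
SMA	MCC	increased	10.05	0.37	0.34	decreased	0.93	1.01	increased
STG	MTG	increased	10.27	NA	NA	ns	NA	NA	ns
CB8	CB9	increased	2.73	NA	NA	ns	0.90	0.83	decreased
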