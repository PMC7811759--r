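node_a	node_b	direction	count_change	fa_contra	fa_ipsi	fa_sig	md_contra	md_ipsi	md_sig
MFG	SFGmedial	increased	12.6	NA	NA	ns	NA	NA	ns
CAL	LING	increased	5	NA	NA	ns	NA	NA	ns
CAL	SOG	increased	1.8	NA	NA	ns	NA	NA	ns
CUN	SOG	increased	4.8	NA	NA	ns	NA	NA	ns
CUN	MOG	increased	6.4	NA	NA	ns	NA	NA	ns
PoCG	SMG	increased	17.2	0.35	0.24	decreased	0.89	1.05	increased
INS	STG	increased	17.4	NA	NA	ns	NA	NA	ns
INS	MTG	increased	12.4	NA	NA	ns	NA	NA	ns
SMG	STG	increased	11	0.33	0.24	decreased	NA	NA	ns
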