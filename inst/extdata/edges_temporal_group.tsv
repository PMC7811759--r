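node_a	node_b	direction	count_change	fa_contra	fa_ipsi	fa_sig	md_contra	md_ipsi	md_sig
IFGoperc	ROL	increased	6	0.36	0.32	decreased	0.89	0.98	increased
IFGtriang	INS	increased	11	NA	NA	ns	0.91	1.00	increased
ROL	INS	increased	17.83	0.33	0.28	decreased	0.93	1.08	increased
SMA	MCC	increased	23.17	NA	NA	ns	NA	NA	ns
CAL	LING	increased	7.17	NA	NA	ns	NA	NA	ns
CUN	SOG	increased	4.83	NA	NA	ns	NA	NA	ns
LING	IOG	increased	4.17	NA	NA	ns	NA	NA	ns
MOG	IOG	increased	8.5	NA	NA	ns	NA	NA	ns
HIP	FFG	increased	17.17	0.34	0.29	decreased	NA	NA	ns
PoCG	SPG	increased	11.33	NA	NA	ns	NA	NA	ns
PoCG	SMG	increased	12.17	0.36	0.33	decreased	0.84	0.89	increased
INS	PUT	increased	11.83	NA	NA	ns	NA	NA	ns
ROL	STG	increased	11	0.35	0.25	decreased	0.89	1.12	increased
ROL	MTG	increased	13.17	0.41	0.30	decreased	0.83	1.03	increased
HIP	ITG	increased	4.67	0.38	0.31	decreased	NA	NA	ns
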