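group_label	atom_a	atom_b	distance_A	b_a	b_b
groove 1	NCH	W204	3.2	64	32
groove 1	W204	W203	3.0	32	32
groove 1	W203	OP2 dG10	2.9	32	32
groove 1	W203	W227	3.4	32	45
groove 1	W227	OAF	2.5	45	29
groove 1	W251	OP2 dG9	2.9	27	30
groove 1	W204	N2 dG4	2.9	32	20
groove 1	W204	W251	2.8	32	27
groove 2	NCA	OP2 dT11	3.1	46	35
groove 2	NCE	W217	2.7	40	46
groove 2	W217	W218	2.6	46	48
groove 2	W218	W219	3.0	48	43
groove 2	W219	ODX	2.7	43	31
groove 2	W218	OP2 dG16	3.4	48	45
groove 3	NCG	W220	2.9	48	50
groove 3	W219	W220	2.9	43	50
groove 4	NCF	OP2 dG4	2.9	58	39
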