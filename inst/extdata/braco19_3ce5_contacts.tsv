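group_label	atom_a	atom_b	distance_A	b_a	b_b
groove 1	N7	W52	2.7	11	21
groove 1	W52	N3 dT24	2.9	21	12
groove 1	W52	O6 dG5	3.0	21	18
groove 1	W52	W53	3.1	21	33
groove 1	W53	O2 dT24	3.3	33	18
groove 1	W53	O52	3.1	33	14
groove 2	W56	N39	3.4	23	27
groove 2	N17	W55	3.0	14	38
groove 2	W55	O2 dT12	3.3	38	17
groove 4	N21	O4 dT24	3.0	13	17
groove 4	N47	W41	3.0	21	28
groove 4	W41	W44	2.9	28	29
groove 4	W44	OP2 dG23	2.5	29	21
groove 4	W41	N2 dG17	2.9	28	18
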