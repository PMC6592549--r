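bw_label	chain	resnum	resname
1.39	A	40	LEU
1.40	A	41	ALA
1.41	A	42	PHE
1.42	A	43	VAL
2.50	A	80	ALA
2.51	A	81	LEU
2.52	A	82	TYR
2.53	A	83	ALA
3.31	A	113	VAL
3.32	A	114	ASP
3.33	A	115	TYR
3.34	A	116	LEU
4.55	A	165	ALA
4.56	A	166	TYR
4.57	A	167	LEU
4.58	A	168	VAL
5.45	A	205	LEU
5.46	A	206	GLU
5.47	A	207	ALA
5.48	A	208	TYR
6.48	A	371	TRP
6.49	A	372	ALA
6.50	A	373	LEU
6.51	A	374	TYR
7.39	A	398	PHE
7.40	A	399	VAL
7.41	A	400	ALA
7.42	A	401	LEU
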