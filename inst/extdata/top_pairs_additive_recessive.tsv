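chr1	gene1	rs1	chr2	gene2	rs2	ap	ci_lo	ci_hi	p	permuted_p	paf	auc	ca00	co00	ca01	co01	ca10	co10	ca11	co11	recoding
9	RNF20	rs16920473	12	GRIN2B	rs2216127	0.69	0.42	0.97	7.65E-7	0.56	0.149	0.5238	377	446	1296	1305	12	14	46	14	identity
4	ARHGAP10	rs4835456	11	GRIK4	rs4936540	0.72	0.42	1.02	2.70E-6	0.72	0.148	0.5136	1105	1176	22	23	582	571	22	6	identity
4	ARHGAP10	rs6824449	16	SLC6A2	rs192303	-1.28	-1.85	-0.72	8.30E-6	0.86	0.149	0.5319	1293	1414	208	159	184	144	16	32	flip_both
16	GRIN2A	rs4782040	11	GRIK4	rs11218032	-0.99	-1.43	-0.55	8.73E-6	0.87	0.149	0.5211	1244	1306	122	126	250	207	9	32	flip_both
12	GRIN2B	rs3764030	5	HTR4	rs6865654	0.68	0.37	0.99	1.27E-5	0.91	0.148	0.5063	1363	1423	47	48	231	235	22	7	identity
11	GRIK4	rs7939968	4	NR3C2	rs12641471	0.52	0.28	0.76	2.03E-5	0.94	0.144	0.5170	1088	1165	192	186	275	292	69	32	identity
4	ARHGAP10	rs6824449	16	GRIN2A	rs11640235	-1.01	-1.56	-0.55	3.60E-5	0.98	0.149	0.5204	1355	1435	210	163	105	108	8	25	flip_both
11	GRIK4	rs7939968	4	NR3C2	rs4835508	0.51	0.27	0.75	3.77E-5	0.98	0.143	0.5186	1029	1118	185	179	275	295	70	33	identity
11	GRIK4	rs7939968	4	ARHGAP10	rs12641157	0.64	0.33	0.94	5.05E-5	0.99	0.148	0.5178	1347	1444	260	229	93	95	26	8	identity
3	HTR3C	rs6766410	6	LAMA4	rs6913656	-0.84	-1.25	-0.43	5.48E-5	0.99	0.148	0.5216	1210	1279	243	207	217	218	21	49	flip_both
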