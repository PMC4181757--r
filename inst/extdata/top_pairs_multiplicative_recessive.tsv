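chr1	gene1	rs1	chr2	gene2	rs2	or	ci_lo	ci_hi	p	permuted_p	paf	auc	ca00	co00	ca01	co01	ca10	co10	ca11	co11
5	GRIA1	rs574071	11	HTR3B	rs1672717	0.52	0.39	0.71	2.72E-5	0.70	0.132	0.5433	371	473	701	646	222	182	305	346
4	NR3C2	rs7691663	5	GRIA1	rs9686702	1.84	1.38	2.44	3.28E-5	0.76	0.117	0.5375	270	211	313	374	445	516	703	679
3	GSK3B	rs1719889	16	GRIN2A	rs1102967	0.55	0.41	0.73	3.30E-5	0.76	0.139	0.5423	228	345	569	517	308	289	534	552
11	GRIA4	rs17104807	22	COMT	rs2020917	2.39	1.57	3.63	4.56E-5	0.86	0.118	0.5386	98	86	643	719	86	149	848	784
12	GRIN2B	rs3764030	16	GRIN2A	rs1868289	4.99	2.26	11.03	6.95E-5	0.96	0.133	0.5169	41	13	29	44	695	742	948	970
5	GRIA1	rs574071	16	GRIN2A	rs1070548	2.21	1.48	3.31	1.17E-4	0.99	0.142	0.5284	517	532	819	860	70	110	186	135
9	NTRK2	rs1624327	16	GRIN2A	rs1097784	1.94	1.38	2.72	1.19E-4	0.99	0.138	0.5332	562	581	639	662	128	186	237	178
4	ARHGAP10	rs6824449	16	SLC6A2	rs192303	0.27	0.14	0.54	1.68E-4	1.0	0.119	0.5319	1293	1414	208	159	184	144	16	32
6	GRIK2	rs7770500	6	LAMA4	rs2072019	2.06	1.41	3.00	1.76E-4	1.0	0.116	0.5133	139	102	666	719	119	164	792	781
9	SLC1A1	rs7022369	5	GRIA1	rs12658202	1.92	1.36	2.71	1.98E-4	1.0	0.067	0.5285	100	147	281	326	399	352	957	952
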