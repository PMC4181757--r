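chr1	gene1	rs1	chr2	gene2	rs2	or	ci_lo	ci_hi	p	permuted_p	paf	auc	ca00	co00	ca01	co01	ca10	co10	ca11	co11
4	GRIA2	rs17244157	16	GRIN2A	rs1861192	0.44	0.30	0.64	2.39E-5	0.85	0.120	0.5442	712	838	175	120	589	539	98	120
9	SLC1A1	rs10974611	6	LAMA4	rs2032568	0.47	0.38	0.67	3.60E-5	0.92	0.125	0.5389	536	624	154	116	699	682	145	195
12	GRIN2B	rs12371702	9	GRIN3A	rs13292935	0.41	0.26	0.62	3.72E-5	0.95	0.114	0.5375	1003	1122	442	377	236	202	51	82
4	GRIA2	rs17244157	16	GRIN2A	rs16966731	0.45	0.31	0.66	3.78E-5	0.95	0.127	0.5322	572	642	147	88	798	808	135	162
21	GRIK1	rs379182	11	GRIK4	rs17124632	0.24	0.12	0.48	4.41E-5	0.97	0.148	0.5244	80	111	46	14	1165	1221	357	342
10	RPP30	rs11186343	7	HTR5A	rs2919435	2.49	1.60	3.89	5.51E-5	0.98	0.130	0.5295	145	97	58	89	951	1028	558	555
3	NR1I2	rs6438549	12	GRIN2B	rs12823982	0.45	0.30	0.67	7.17E-5	0.99	0.114	0.5333	927	1011	222	182	505	473	67	105
13	HTR2A	rs666693	22	COMT	rs8185002	3.05	1.75	5.31	8.82E-5	0.99	0.148	0.5325	596	548	34	61	927	1011	83	58
4	NR3C2	rs7691663	5	GRIA1	rs1422897	2.09	1.44	3.02	1.02E-4	0.99	0.110	0.5310	124	85	445	490	185	237	977	964
19	GRIK5	rs4803523	5	GRIA1	rs13359392	2.31	1.51	3.55	1.27E-4	1.0	0.144	0.5350	548	487	58	90	962	1068	161	135
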