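chr1	gene1	rs1	chr2	gene2	rs2	ap	ci_lo	ci_hi	p	permuted_p	paf	auc	ca00	co00	ca01	co01	ca10	co10	ca11	co11	recoding
4	ARHGAP10	rs9332471	4	ARHGAP10	rs6845865	0.58	0.39	0.78	9.10E-9	0.14	0.147	0.5153	1009	1073	169	174	475	500	78	33	identity
6	HTR1E	rs6922679	16	GRIN2A	rs17570500	0.71	0.42	1.002	1.92E-6	0.57	0.142	0.5046	48	50	20	6	1332	1388	310	321	flipA
4	ARHGAP10	rs9332471	4	ARHGAP10	rs2306910	0.63	0.37	0.89	2.40E-6	0.61	0.149	0.5136	1201	1273	190	182	233	238	35	12	identity
4	ARHGAP10	rs9991394	4	ARHGAP10	rs12645249	0.59	0.34	0.84	2.58E-6	0.63	0.146	0.5173	1162	1257	332	326	154	158	47	18	identity
9	GRIN3A	rs7873495	11	GRIK4	rs10892635	-1.08	-1.56	-0.59	1.26E-5	0.90	0.139	0.5216	290	258	10	30	1308	1390	122	105	swap_flip
12	GRIN2B	rs12371702	9	GRIN3A	rs13292935	-0.92	-1.35	-0.50	1.89E-5	0.95	0.146	0.5375	1003	1122	442	377	236	202	51	82	flip_both
12	GRIN2B	rs11832404	4	NR3C2	rs982076	-1.23	-1.81	-0.65	3.49E-5	0.99	0.142	0.5266	257	182	10	24	1268	1367	92	86	swap_flip
12	GRIN2B	rs11832404	11	GRIK4	rs7928347	-1.27	-1.89	-0.66	5.24E-5	0.99	0.142	0.5300	255	185	7	18	1234	1332	87	78	swap_flip
4	ARHGAP10	rs9332471	9	SLC1A1	rs184204	0.53	0.27	0.79	6.28E-5	0.99	0.145	0.5157	1212	1292	194	183	271	282	53	23	identity
5	GRIA1	rs17114975	12	GRIN2B	rs1012587	0.64	0.33	0.95	6.54E-5	0.99	0.129	0.5084	83	79	24	8	1381	1448	241	245	flipA
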