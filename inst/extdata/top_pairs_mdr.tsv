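chr1	gene1	rs1	chr2	gene2	rs2	ba	paf	or	ci_lo	ci_hi	p	high_cases	high_controls	low_cases	low_controls	tpr	fpr
12	GRIN2B	rs1012587	3	HTR3C	rs6762938	0.5513	0.0980	1.51	1.32	1.73	1.168E-09	907	751	825	1032	0.524	0.421
16	GRIN2A	rs8045893	3	HTR3C	rs6762938	0.5498	0.0900	1.49	1.30	1.71	4.452E-09	1033	887	699	896	0.596	0.497
6	HTR1E	rs17222848	5	GRIA1	rs17515709	0.5480	0.0950	1.47	1.28	1.68	1.707E-08	933	790	799	993	0.539	0.443
11	GRIA4	rs609665	6	GRIK2	rs2518171	0.5476	0.0917	1.46	1.28	1.68	2.051E-08	982	842	750	941	0.567	0.472
6	GRIK2	rs17828670	3	GSK3B	rs6771023	0.5470	0.0894	1.46	1.28	1.67	2.757E-08	1021	884	711	899	0.589	0.554
13	HTR2A	rs9526240	11	BDNF	rs6265	0.5468	0.0912	1.45	1.27	1.66	3.643E-08	984	847	748	936	0.568	0.475
16	SLC6A2	rs1814270	6	FKBP5	rs9462104	0.5465	0.1020	1.46	1.28	1.68	3.031E-08	809	668	923	1115	0.467	0.375
13	HTR2A	rs17288723	9	GRIN3A	rs11788456	0.5454	0.0937	1.44	1.26	1.64	8.039E-08	936	802	796	981	0.540	0.500
12	GRIN2B	rs10845847	12	GRIN2B	rs12301788	0.5454	0.0809	1.48	1.29	1.71	2.458E-08	1180	1053	552	730	0.681	0.591
17	SLC6A4	rs2020939	6	GRIK2	rs2749074	0.5448	0.1012	1.44	1.26	1.65	8.982E-08	812	677	920	1106	0.469	0.380
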