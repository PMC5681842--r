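rsid	chrom	pos	func	gene	effect_allele	other_allele	eaf_afr	eaf_amr	eaf_eas	eaf_eur	eaf_sas	eaf_global	gwas_pvalue
rs1011731	1	172346548	intron	DNM3	G	A	0.90	0.36	0.13	0.42	0.43	0.48	1.0E-17
rs10146997	14	79945162	intron	NRXN3	G	A	0.41	0.20	0.00	0.21	0.11	0.20	5.0E-08
rs10150332	14	79936964	intron	NRXN3	C	T	0.44	0.20	0.00	0.21	0.11	0.21	3.0E-11
rs10182181	2	25150296	intergene	ADCY3 - DNAJC27	G	A	0.91	0.38	0.44	0.47	0.48	0.57	1.0E-17
rs10195252	2	165513091	intron	LOC101929615	T	C	0.20	0.74	0.90	0.56	0.79	0.60	2.0E-24
rs10261878	7	25950545	intergene	UBA52P1 - MIR148A	C	A	0.34	0.89	0.96	0.94	0.96	0.78	1.0E-10
rs1055144	7	25871109	ncRNA	LOC100506236	T	C	0.04	0.16	0.43	0.21	0.46	0.25	1.0E-24
rs10767664	11	27725986	intron	BDNF	A	T	0.95	0.83	0.51	0.77	0.70	0.76	5.0E-26
rs10838738	11	47663049	intron	MTCH2	G	A	0.05	0.40	0.28	0.35	0.33	0.26	5.0E-09
rs11030104	11	27684517	intron;intron	BDNF, BDNF-AS	A	G	0.98	0.83	0.51	0.78	0.74	0.78	2.0E-20
rs11847697	14	30515112	intergene	PRKD1 - RPS6P24	T	C	0.41	0.05	0.00	0.05	0.11	0.15	6.0E-11
rs12229654	12	111414461	intergene	MYL2 - CUX2	T	G	1.00	1.00	0.84	1.00	1.00	0.97	5.0E-09
rs1294421	6	6743149	intergene	LY86 - BTF3P7	G	T	0.77	0.50	0.26	0.61	0.40	0.53	2.0E-17
rs13034723	2	190985680	intron	C2orf88	A	G	0.06	0.45	0.69	0.46	0.70	0.45	2.0E-08
rs13389219	2	165528876	intergene	EIF3EP3 - COBLL1	C	T	0.20	0.74	0.90	0.56	0.78	0.60	3.0E-08
rs1443512	12	54342684	intergene	HOXC13 - HOXC12	A	C	0.64	0.21	0.17	0.22	0.32	0.34	6.0E-17
rs1555543	1	96944797	intergene	EEF1A1P11 - NDUFS5P2	C	A	0.39	0.57	0.88	0.58	0.51	0.58	4.0E-10
rs1957894	14	61908111	intron	PRKCH	T	G	0.77	0.13	0.41	0.08	0.11	0.34	3.0E-10
rs2030323	11	27728539	intron	BDNF	C	A	0.95	0.83	0.51	0.77	0.70	0.76	3.0E-22
rs2075064	9	126783847	intron	LHX2	C	T	0.93	0.54	0.58	0.56	0.65	0.68	2.0E-08
rs2307111	5	75003678	missense	POC5	T	C	0.08	0.52	0.47	0.60	0.40	0.38	3.0E-12
rs2568958	1	72765116	intergene	GDI2P2 - RPL31P12	A	G	0.53	0.70	0.93	0.64	0.62	0.68	4.0E-16
rs2815752	1	72812440	intergene	RPL31P12 - KRT8P21	A	G	0.53	0.70	0.93	0.64	0.62	0.68	2.0E-22
rs2890652	2	142959931	intergene	RPS16P3 - KYNU	C	T	0.38	0.09	0.00	0.17	0.06	0.16	1.0E-10
rs29941	19	34309532	intergene	KCTD15 - RPS4XP20	G	A	0.85	0.61	0.24	0.67	0.62	0.61	7.0E-12
rs3101336	1	72751185	intergene	GDI2P2 - RPL31P12	C	T	0.53	0.70	0.93	0.64	0.62	0.68	1.0E-13
rs3810291	19	47569003	3'-UTR	ZC3H4	A	G	0.09	0.51	0.27	0.66	0.40	0.36	2.0E-12
rs591166	18	57841589	intergene	RPS3AP49 - MC4R	A	T	0.82	0.38	0.22	0.43	0.49	0.50	7.0E-14
rs6265	11	27679916	missense;ncRNA	BDNF, BDNF-AS	C	T	0.99	0.85	0.51	0.80	0.80	0.80	5.0E-10
rs6545814	2	25131316	intron	ADCY3	G	A	0.85	0.35	0.42	0.43	0.46	0.54	1.0E-13
rs671	12	112241766	missense	ALDH2	G	A	1.00	1.00	0.83	1.00	1.00	0.96	3.0E-11
rs713586	2	25158008	intergene	ADCY3 - DNAJC27	C	T	0.92	0.38	0.48	0.47	0.48	0.58	6.0E-22
rs718314	12	26453283	intergene	SSPN - ITPR2	G	A	0.19	0.49	0.70	0.24	0.24	0.35	1.0E-17
rs7184597	16	28921809	intron	RABEP2	T	C	0.01	0.45	0.12	0.28	0.16	0.18	7.0E-09
rs7359397	16	28885659	downstream	SH2B1	T	C	0.01	0.47	0.12	0.33	0.19	0.19	2.0E-20
rs7531118	1	72837239	intergene	RPL31P12 - KRT8P21	C	T	0.05	0.38	0.26	0.55	0.29	0.29	2.0E-17
rs7586879	2	25116977	intron	ADCY3	T	C	0.86	0.29	0.37	0.35	0.43	0.50	4.0E-08
rs7708584	5	153543466	intergene	MFAP3 - GALNT10	A	G	0.26	0.63	0.96	0.44	0.47	0.53	5.0E-14
rs9356744	6	20685486	intron	CDKAL1	T	C	0.30	0.67	0.61	0.68	0.71	0.57	5.0E-13
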