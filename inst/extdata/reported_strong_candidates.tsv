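locus	index_snp	variant_id	mean_imputation_r2	r2_with_index	predicted_gene	location_class	n_open_chromatin_lines	open_chromatin_crc_line	n_histone_cancer_lines	n_histone_normal_lines	histone_normal_colorectal	proteins_bound	protein_binding_crc_line	altered_motifs	conserved
5q31.1	rs647161	rs1366111	0.89	0.57	PITX1	intronic	2	0	2	0	1	POL2;EGR1	0	Zfx	0
8q24	rs6983267	rs6983267	0.95	index	MYC	intergenic	1	1	1	2	1	TCF4;P300;FOXA1;RXRA;SP1	1	AP-1;Sox;TCF4	1
11q13.4	rs3824999	rs3824999	0.99	index	POLD3	intronic	4	0	0	2	1	JUND	0	AP-3;Evi-1;Mef2	0
11q23	rs3802842	rs7130173	0.95	0.93	Unknown	intronic	31	1	0	0	1	RAD21;SMC3;YY1;CTCF	0	GSP1;SRF	0
12p13.32	rs3217901	rs3217827	0.85	0.61	CCND2	intronic	1	0	0	0	1	RAD21;CTCF	0	.	0
12q24.21	rs59336	rs71807	0.89	0.86	TBX3	intergenic	1	0	2	4	1	BAF155;HAE2F1;CTCF	0	.	0
12q24.21	rs59336	rs484443	0.91	0.90	TBX3	intronic	8	0	1	2	1	P300;USF1	0	RREB-1;Rad21	0
14q22.2	rs4444235	rs2071047	1.00	0.75	BMP4	intronic	9	0	3	3	1	TCF4	1	BCL;HNF4;RXRA	0
14q22.2	rs4444235	rs10130587	0.74	0.67	BMP4	intronic	2	0	3	3	1	GATA3	0	5_motifs	0
14q22.2	rs4444235	rs35107139	0.82	0.64	BMP4	intronic	2	0	3	3	1	GATA3	0	12_motifs	0
15q13	rs4779584	rs2293582	0.94	0.71	GREM1	intronic	4	0	3	5	1	POL2	0	.	0
15q13	rs4779584	rs2293581	0.97	0.66	GREM1	intronic	36	0	4	5	1	SUZ12	0	.	0
15q13	rs4779584	rs1406389	0.97	0.66	GREM1	intergenic	12	0	3	4	1	SUZ12	0	Irf;SIX5	0
18q21	rs4939827	rs11874392	0.93	1.00	SMAD7	intronic	4	0	3	1	1	BATF;others	0	.	1
18q21	rs4939827	rs4939567	0.91	1.00	SMAD7	intronic	1	0	4	3	1	MAFK	0	RREB-1;VDR_2	1
18q21	rs4939827	rs34007497	0.91	0.57	SMAD7	intronic	22	0	2	4	1	CTCF;STAT1	0	4_motifs	0
19q13.1	rs10411210	rs10411210	0.94	index	RHPN2	intronic	48	1	2	1	1	POL2;others	0	Mef2;STAT	1
20p12.3	rs961253	rs966817	1.00	0.87	BMP2	intergenic	18	0	0	1	0	CJUN	0	Evi-1;FAC1;GLI	1
20p12.3	rs4813802	rs4813802	0.86	index	BMP2	intergenic	10	0	2	2	1	CTCF;others	0	.	1
20p12.3	rs4813802	rs6085661	0.89	0.76	BMP2	intergenic	19	0	1	0	1	MAX;others	0	BCL;NRSF;VDR	1
20q13.33	rs4925386	rs1741634	0.96	0.80	LAMA5	intronic	7	0	0	2	1	GR	0	EWSR1-FLI1	0
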