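locus	index_snp	n_snps_region	top_snp	position_b37	gene_region	r2_with_index	alleles	ref_allele_freq	or	ci_lower	ci_upper	p	p_het
1q25.3	rs10911251	1886	rs6669796	183082825	LAMC1	0.87	G/C	0.56	1.11	1.07	1.16	5.8e-07	0.60
1q41	rs6687758	1885	rs143030473	222161943	DUSP10/CICP13	<0.2	C/T	0.99	1.97	1.35	2.87	4.5e-04	0.92
1q41	rs6691170	2096	rs143030473	222161943	DUSP10/CICP13	<0.2	C/T	0.99	1.97	1.35	2.87	4.5e-04	0.92
2q32.3	rs11903757	1536	rs6731095	192589442	NABP1/SDPR	1.00	A/G	0.84	0.89	0.84	0.95	2.3e-04	0.11
3q26.2	rs10936599	1651	rs2421771	169411370	MECOM/MYNN	<0.2	C/T	0.96	1.21	1.05	1.40	7.5e-03	0.92
5q31.1	rs647161	1499	rs2193941	134469594	PITX1/H2AFY	0.57	G/A	0.72	1.09	1.05	1.14	4.0e-05	0.92
6p21	rs1321311	2364	rs13215272	36589502	SRSF3/CDKN1A	<0.2	C/T	0.73	1.10	1.04	1.15	5.3e-04	0.08
8q23.3	rs16892766	1432	rs16888589	117635602	TRPS1/EIF3H	0.92	A/G	0.91	0.80	0.75	0.86	3.3e-10	0.71
8q24	rs6983267	2257	rs7013278	128414892	SRRM1P1/POU5F1B/MYC	0.40	C/T	0.66	0.88	0.85	0.92	7.8e-11	0.74
9p24	rs719725	1907	rs7875812	6364533	TPD52L3/UHRF2	1.00	A/T	0.63	1.09	1.04	1.13	7.9e-05	0.74
10p14	rs10795668	2363	rs1537603	8734295	KRT8P16/TCEB1P3	0.45	C/T	0.50	1.06	1.02	1.10	1.2e-03	0.79
11q13.4	rs3824999	1788	rs72977282	74300441	LIPT2/POLD3	0.59	T/A	0.59	0.92	0.88	0.95	9.8e-06	0.81
11q23	rs3802842	1830	rs7130173	111154072	C11orf93	0.95	C/A	0.73	0.89	0.85	0.93	2.7e-08	0.38
12p13.32	rs10774214	1656	rs3217874	4400808	CCND2	<0.2	C/T	0.58	0.89	0.85	0.93	3.1e-08	0.78
12p13.32	rs3217810	1571	rs3217874	4400808	CCND2	<0.2	C/T	0.58	0.89	0.85	0.93	3.1e-08	0.78
12p13.32	rs3217901	1539	rs3217874	4400808	CCND2	0.65	C/T	0.58	0.89	0.85	0.93	3.1e-08	0.78
12q13.13	rs11169552	1310	rs7306677	51205763	ATF1	<0.2	C/T	0.62	0.92	0.89	0.96	6.3e-05	0.34
12q13.13	rs7136702	967	rs11169524	51089734	DIP2B	0.67	T/A	0.67	0.92	0.88	0.96	8.5e-05	0.53
12q24.21	rs59336	2072	rs1427760	115100714	TBX5/TBX3	0.71	T/C	0.50	0.90	0.87	0.94	5.0e-07	0.25
14q22.2	rs1957636	1613	rs10130587	54419110	BMP4	<0.2	G/C	0.63	0.89	0.85	0.93	4.1e-08	0.90
14q22.2	rs4444235	1659	rs10130587	54419110	BMP4	0.67	G/C	0.63	0.89	0.85	0.93	4.1e-08	0.90
15q13	rs11632715	1735	rs2293582	33010412	GREM1	0.23	G/A	0.80	0.86	0.82	0.91	1.0e-09	0.38
15q13	rs16969681	1692	rs2293582	33010412	GREM1	0.22	G/A	0.80	0.86	0.82	0.91	1.0e-09	0.38
15q13	rs4779584	1701	rs2293582	33010412	GREM1	0.71	G/A	0.80	0.86	0.82	0.91	1.0e-09	0.38
16q22.1	rs9929218	1867	rs9932005	68822019	CDH1	0.63	C/T	0.76	1.08	1.03	1.13	1.2e-03	0.66
18q21	rs4939827	1931	rs2337113	46452327	SMAD7	0.91	A/G	0.55	1.13	1.09	1.18	1.0e-10	0.25
19q13.1	rs10411210	2307	rs75414102	33302424	TDRD12/SLC7A9	<0.2	G/A	0.99	0.51	0.33	0.79	2.6e-03	0.91
20p12.3	rs2423279	1901	rs118184022	7719449	BMP2/HAO1	<0.2	C/T	0.98	0.58	0.41	0.83	2.8e-03	0.94
20p12.3	rs4813802	1825	rs6085662	6698372	FERMT1/BMP2	1.00	G/C	0.65	0.91	0.87	0.95	5.1e-06	0.30
20p12.3	rs961253	1990	rs56083061	6430696	FERMT1/BMP2	0.28	G/A	0.79	0.90	0.85	0.94	5.6e-06	0.76
20q13.33	rs4925386	2173	rs1760073	60926106	LAMA5	0.81	G/A	0.67	1.08	1.04	1.12	1.9e-04	0.88
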