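mirna	p_value	fold_change	direction	nr_mean	cr_mean	chromosome	accession
hsa-miR-31	0.0091	2.21	down	1.14	2.51	chr9	MIMAT0000089
hsa-miR-125b	0.0233	1.72	down	1.17	2.02	chr11	MIMAT0000423
hsa-miR-10a	0.0234	1.85	down	1.08	1.99	chr17	MIMAT0000253
hsa-miR-181d	0.0452	1.29	down	1.49	1.92	chr19	MIMAT0002821
hsa-miR-126*	0.0462	1.18	down	1.14	1.35	chr9	MIMAT0000444
hsa-miR-21*	0.0068	3.65	up	8.13	2.23	chr17	MIMAT0004494
hsa-miR-222	0.0096	2.12	up	70.59	33.31	chrX	MIMAT0000279
hsa-miR-28-3p	0.0201	3.38	up	5.04	1.49	chr3	MIMAT0004502
hsa-miR-194	0.0347	2.40	up	14.59	6.08	chr1	MIMAT0000460
hsa-miR-148a	0.0414	3.44	up	73.41	21.33	chr7	MIMAT0000243
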