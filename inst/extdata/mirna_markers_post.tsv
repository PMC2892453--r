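mirna	p_value	fold_change	direction	nr_mean	cr_mean	chromosome	accession
hsa-miR-138-2*	0.0142	1.91	down	1.39	2.65	chr16	MIMAT0004596
hsa-miR-21*	0.0168	3.11	up	9.60	3.09	chr17	MIMAT0004494
hsa-miR-148a	0.0188	2.77	up	119.81	43.27	chr7	MIMAT0000243
hsa-miR-221*	0.0212	1.96	up	9.75	4.97	chrX	MIMAT0004568
hsa-miR-21	0.0244	2.29	up	15079.56	6580.23	chr17	MIMAT0000076
hsa-miR-192	0.0266	1.95	up	35.14	18.04	chr11	MIMAT0000222
hsa-miR-194	0.0378	2.20	up	17.70	8.04	chr1	MIMAT0000460
hsa-miR-801	0.0408	1.81	up	44.94	24.83	chr1	MIMAT0004209
hsa-miR-598	0.0428	2.18	up	9.88	4.53	chr8	MIMAT0003266
hsa-miR-20a*	0.0448	1.99	up	37.27	18.77	chr13	MIMAT0004493
hsa-miR-222	0.0486	1.97	up	52.07	26.38	chrX	MIMAT0000279
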