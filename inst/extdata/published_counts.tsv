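# table: published_counts
# version: 2026.1
# Carrier counts and printed statistics of the study's association
# tables: the KIR-allele screen and the receptor-ligand interaction
# screen in the KIR AA / Bx genotype strata, plus the C2-ligand
# comparison. reproducible = printed OR/CI/p are arithmetically
# consistent with the printed counts (zero-cell rows and rows whose
# percentages contradict their counts are FALSE).
feature	type	stratum	allele	ligand	case_cohort	control_n	control_N	case_n	case_N	printed_pct_control	printed_pct_case	printed_or	printed_ci_lo	printed_ci_hi	printed_p	printed_pc	reproducible
2DL1*00201	allele	AA	2DL1*00201	NA	ALL	48	167	34	155	28.7	21.9	0.70	0.42	1.16	0.16	NA	TRUE
2DL1*00201	allele	AA	2DL1*00201	NA	AML	48	167	31	162	28.7	19.1	0.59	0.35	0.98	0.04	0.41	TRUE
2DL1*069	allele	AA	2DL1*069	NA	ALL	0	167	5	155	0	3.2	0.97	0.94	1.00	0.06	NA	FALSE
2DL1*069	allele	AA	2DL1*069	NA	AML	0	167	6	162	0	3.7	0.96	0.93	0.99	0.04	0.36	FALSE
2DL3*00201	allele	AA	2DL3*00201	NA	ALL	47	167	33	155	28.1	21.3	0.69	0.41	1.15	0.16	NA	TRUE
2DL3*00201	allele	AA	2DL3*00201	NA	AML	47	167	29	162	28.1	17.9	0.56	0.33	0.94	0.03	0.50	TRUE
3DL3*001	allele	AA	3DL3*001	NA	ALL	14	167	5	155	8.4	3.8	0.43	0.15	1.23	0.11	NA	FALSE
3DL3*001	allele	AA	3DL3*001	NA	AML	14	167	2	162	8.4	1.3	0.14	0.03	0.65	0.004	0.06	FALSE
3DL3*009	allele	AA	3DL3*009	NA	ALL	49	167	59	155	29.3	44.7	1.95	1.21	3.14	0.01	0.08	FALSE
3DL3*009	allele	AA	3DL3*009	NA	AML	49	167	72	162	29.3	47.1	2.14	1.35	3.39	0.001	0.016	FALSE
2DL1*00201+C2	interaction	AA	2DL1*00201	C2	ALL	15	167	4	155	9.0	2.6	0.27	0.09	0.83	0.01	NA	TRUE
2DL1*00201+C2	interaction	AA	2DL1*00201	C2	AML	15	167	7	162	9.0	4.3	0.46	0.18	1.15	0.09	NA	TRUE
2DL1*00302+C2	interaction	AA	2DL1*00302	C2	ALL	51	167	39	155	30.5	25.2	0.76	0.47	1.25	0.28	NA	TRUE
2DL1*00302+C2	interaction	AA	2DL1*00302	C2	AML	51	167	29	162	30.5	17.9	0.50	0.30	0.83	0.008	NA	TRUE
2DL3*00201+C1	interaction	AA	2DL3*00201	C1	ALL	47	167	33	155	28.1	21.3	0.69	0.41	1.15	0.16	NA	TRUE
2DL3*00201+C1	interaction	AA	2DL3*00201	C1	AML	47	167	29	162	28.1	17.9	0.56	0.33	0.94	0.03	NA	TRUE
3DL1*00501+Bw4-80I	interaction	AA	3DL1*00501	Bw4-80I	ALL	24	167	15	155	14.4	9.7	0.64	0.32	1.27	0.2	NA	TRUE
3DL1*00501+Bw4-80I	interaction	AA	3DL1*00501	Bw4-80I	AML	24	167	9	162	14.4	5.6	0.35	0.16	0.78	0.008	NA	TRUE
2DL1*004+C2	interaction	Bx	2DL1*004	C2	ALL	0	139	9	163	0	5.5	0.94	0.91	0.98	0.01	NA	FALSE
2DL1*004+C2	interaction	Bx	2DL1*004	C2	AML	0	139	6	174	0	3.4	0.97	0.94	0.99	0.07	NA	FALSE
C2	ligand	AA	NA	C2	AML	52	167	29	162	31.1	17.9	NA	NA	NA	0.005	0.01	TRUE
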