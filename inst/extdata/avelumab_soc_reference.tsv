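soc	n	ror	ror_lo95	ror_hi95	prr	prr_lo95	prr_hi95	chi2	ic	ic025	ebgm	ebgm05
General disorders and administration site conditions	868	1.22	1.13	1.32	1.17	1.1	1.24	27.62	0.23	0.13	1.17	1.1
Gastrointestinal disorders	324	0.95	0.84	1.06	0.95	0.86	1.05	0.94	-0.07	-0.24	0.95	0.86
Respiratory, thoracic, and mediastinal disorders	310	1.68	1.49	1.88	1.62	1.47	1.79	78.04	0.7	0.53	1.62	1.47
Nervous system disorders	294	0.9	0.8	1.01	0.91	0.81	1.02	3.14	-0.14	-0.31	0.91	0.82
Investigations	284	1.19	1.05	1.34	1.17	1.04	1.32	7.82	0.23	0.06	1.17	1.06
Injury, poisoning, and procedural complications	253	0.52	0.46	0.59	0.55	0.49	0.62	103.73	-0.86	-1.04	0.55	0.5
Musculoskeletal and connective tissue disorders	182	0.85	0.73	0.98	0.85	0.74	0.97	4.9	-0.23	-0.44	0.85	0.75
Infections and infestations	165	0.72	0.62	0.84	0.73	0.62	0.85	17.07	-0.45	-0.67	0.73	0.64
Skin and subcutaneous tissue disorders	158	0.65	0.56	0.76	0.67	0.57	0.78	28.15	-0.59	-0.82	0.67	0.58
Cardiac disorders	146	1.74	1.47	2.05	1.71	1.46	2	43.91	0.77	0.54	1.71	1.49
Renal and urinary disorders	128	1.58	1.32	1.88	1.56	1.31	1.86	26.27	0.64	0.39	1.56	1.35
Metabolism and nutrition disorders	122	1.47	1.23	1.76	1.45	1.22	1.73	17.69	0.54	0.28	1.45	1.25
Hepatobiliary disorders	114	3.44	2.86	4.15	3.37	2.83	4.02	191.64	1.75	1.49	3.37	2.88
Blood and lymphatic system disorders	114	1.69	1.41	2.04	1.67	1.4	1.99	31.51	0.74	0.48	1.67	1.43
Endocrine disorders	111	10.65	8.82	12.86	10.38	8.7	12.38	941.99	3.37	3.1	10.37	8.85
Vascular disorders	111	1.4	1.16	1.69	1.39	1.17	1.66	12.29	0.47	0.2	1.39	1.19
Immune system disorders	57	1.14	0.88	1.48	1.14	0.88	1.47	0.99	0.19	-0.19	1.14	0.92
Psychiatric disorders	49	0.21	0.16	0.28	0.22	0.17	0.29	146.29	-2.2	-2.6	0.22	0.17
Eye disorders	37	0.45	0.32	0.62	0.45	0.33	0.62	24.76	-1.14	-1.6	0.45	0.35
Ear and labyrinth disorders	9	0.49	0.26	0.95	0.49	0.26	0.94	4.69	-1.02	-1.91	0.49	0.29
Reproductive system and breast disorders	5	0.17	0.07	0.4	0.17	0.07	0.41	20.75	-2.57	-3.73	0.17	0.08
Congenital, familial, and genetic disorders	4	0.35	0.13	0.94	0.35	0.13	0.93	4.8	-1.51	-2.77	0.35	0.15
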