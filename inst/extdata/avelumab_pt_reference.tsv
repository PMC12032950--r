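pt	n	ror	ror_lo95	ror_hi95	prr	prr_lo95	prr_hi95	chi2	ic	ic025	ebgm	ebgm05
Chills	65	8.83	6.91	11.29	8.7	6.88	11.01	443.58	3.12	2.77	8.7	7.08
Interstitial lung disease	63	20.1	15.67	25.79	19.8	15.35	25.55	1122.58	4.3	3.95	19.75	16.03
Thrombocytopenia	35	4.98	3.57	6.95	4.95	3.55	6.91	110.45	2.31	1.83	4.95	3.74
Hypothyroidism	31	15.49	10.88	22.07	15.38	10.81	21.89	416.29	3.94	3.44	15.36	11.42
Myositis	24	48.16	32.21	72.03	47.88	32.35	70.86	1095.38	5.57	5	47.61	34
Renal impairment	23	3.93	2.61	5.92	3.91	2.59	5.9	49.93	1.97	1.39	3.91	2.78
Neuropathy peripheral	22	3.32	2.18	5.04	3.3	2.19	4.98	35.39	1.72	1.13	3.3	2.33
Pneumonitis	21	11.07	7.21	17	11.01	7.15	16.95	191.05	3.46	2.85	11	7.68
Myocarditis	21	27.17	17.68	41.74	27.03	17.56	41.6	524.78	4.75	4.15	26.94	18.81
Colitis	20	7.8	5.03	12.11	7.77	5.05	11.96	117.94	2.96	2.34	7.76	5.37
Respiratory failure	19	4.43	2.82	6.95	4.41	2.81	6.92	50.14	2.14	1.51	4.41	3.02
Pulmonary embolism	19	3.93	2.5	6.16	3.91	2.49	6.14	41.21	1.97	1.33	3.91	2.68
Hepatic function abnormal	19	8.35	5.32	13.11	8.32	5.3	13.06	122.22	3.05	2.42	8.31	5.7
Oxygen saturation decreased	17	4.31	2.68	6.94	4.29	2.68	6.87	42.98	2.1	1.43	4.29	2.88
Pleural effusion	15	4.1	2.47	6.82	4.09	2.46	6.81	35.07	2.03	1.32	4.09	2.68
Hyperthyroidism	14	14.45	8.54	24.43	14.4	8.48	24.45	174.3	3.85	3.11	14.38	9.26
Hematuria	14	6.37	3.77	10.76	6.35	3.74	10.78	63.05	2.67	1.93	6.34	4.09
Alanine aminotransferase increased	13	4.04	2.34	6.96	4.03	2.33	6.98	29.59	2.01	1.25	4.03	2.55
Hypoxia	12	5.4	3.06	9.52	5.39	3.05	9.52	42.86	2.43	1.64	5.38	3.35
Blood creatine phosphokinase increased	12	8.66	4.91	15.27	8.64	4.89	15.25	81.02	3.11	2.32	8.63	5.37
Hepatitis	12	8.04	4.56	14.17	8.02	4.54	14.16	73.68	3	2.22	8.01	4.99
Adrenal insufficiency	12	14.31	8.12	25.23	14.27	8.08	25.19	147.87	3.83	3.05	14.25	8.86
Palmar-plantar erythrodysesthesia syndrome	12	7.25	4.11	12.78	7.23	4.1	12.76	64.42	2.85	2.07	7.23	4.5
Aspartate aminotransferase increased	11	4.17	2.31	7.55	4.17	2.32	7.51	26.47	2.06	1.24	4.16	2.54
Thyroiditis	11	50.27	27.77	91.02	50.14	27.85	90.27	526.57	5.64	4.82	49.84	30.33
Pancreatitis	11	4.06	2.24	7.33	4.05	2.25	7.29	25.26	2.02	1.2	4.05	2.47
Troponin increased	10	22.08	11.86	41.1	22.03	11.77	41.25	200.22	4.46	3.6	21.97	13.06
Hepatotoxicity	10	6.46	3.47	12.01	6.44	3.44	12.06	45.96	2.69	1.83	6.44	3.83
Thyroid disorder	10	9.77	5.25	18.19	9.75	5.21	18.26	78.47	3.28	2.43	9.74	5.79
Cytokine release syndrome	10	7.96	4.28	14.81	7.94	4.24	14.87	60.66	2.99	2.13	7.94	4.72
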