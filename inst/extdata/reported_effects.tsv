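species	breed	gene	snp_id	beta	se	p_value	recommended_allele	recommended_freq	gene_effect	gene_se	gene_p
cattle	Combined	BCMO1	BCMO1.3	-0.536	0.38	0.16	A	0.07	7.57	2.48	0.002
cattle	Combined	BCMO1	BCMO1.11	1.286	0.47	0.006	T	0.04	7.57	2.48	0.002
cattle	Combined	BCMO1	BCMO1.15	-1.937	1.08	0.007	A	0.99	7.57	2.48	0.002
cattle	Combined	BCO2	BCO2.2	1.212	0.87	0.16	G	0.63	5.88	2.84	0.04
cattle	Combined	BCO2	BCO2.4	-0.965	0.92	0.3	A	0.99	5.88	2.84	0.04
cattle	Combined	BCO2	BCO2.5	0.368	0.32	0.25	G	0.88	5.88	2.84	0.04
cattle	Combined	BCO2	BCO2.12	-0.399	0.31	0.2	C	0.24	5.88	2.84	0.04
cattle	Combined	SCARB1	SCARB1.2	0.516	0.32	0.11	C	0.7	3.98	1.73	0.02
cattle	Combined	SCARB1	SCARB1.3	0.715	0.39	0.07	C	0.54	3.98	1.73	0.02
cattle	Combined	SCARB1	SCARB1.8	-0.745	0.37	0.05	T	0.45	3.98	1.73	0.02
cattle	Holstein cross	BCMO1	BCMO1.5	-3.40	1.80	0.06	G	0.98	14.02	5.64	0.01
cattle	Holstein cross	BCMO1	BCMO1.12	0.80	0.57	0.16	G	0.85	14.02	5.64	0.01
cattle	Holstein cross	BCMO1	BCMO1.16	-2.76	2.02	0.17	G	0.01	14.02	5.64	0.01
cattle	Holstein cross	BCO2	BCO2.1	1.80	1.45	0.21	T	0.93	16.58	8.18	0.04
cattle	Holstein cross	BCO2	BCO2.2	2.85	1.59	0.07	G	0.99	16.58	8.18	0.04
cattle	Holstein cross	BCO2	BCO2.6	-1.82	1.68	0.28	A	0.12	16.58	8.18	0.04
cattle	Holstein cross	BCO2	BCO2.11	1.94	1.81	0.29	G	0.97	16.58	8.18	0.04
cattle	Jersey cross	BCO2	BCO2.1	-1.55	1.07	0.15	G	0.28	13.32	9.30	0.01
cattle	Jersey cross	BCO2	BCO2.3	-2.66	1.71	0.13	A	0.02	13.32	9.30	0.01
cattle	Jersey cross	BCO2	BCO2.4	-1.09	0.89	0.21	A	0.63	13.32	9.30	0.01
cattle	Jersey cross	BCO2	BCO2.6	1.36	0.98	0.12	G	0.73	13.32	9.30	0.01
cattle	Jersey cross	SCARB1	SCARB1.3	2.31	1.29	0.07	C	0.68	17.74	4.72	0.0003
cattle	Jersey cross	SCARB1	SCARB1.5	1.18	0.58	0.03	G	0.58	17.74	4.72	0.0003
cattle	Jersey cross	SCARB1	SCARB1.10	3.18	0.92	0.0009	T	0.14	17.74	4.72	0.0003
cattle	Jersey cross	SCARB1	SCARB1.16	-2.19	1.56	0.17	C	0.99	17.74	4.72	0.0003
cattle	Gir	BCMO1	BCMO1.2	-4.72	3.18	0.14	A	0.002	14.1	6.66	0.04
cattle	Gir	BCMO1	BCMO1.3	-1.03	0.64	0.11	A	0.1	14.1	6.66	0.04
cattle	Gir	BCMO1	BCMO1.8	-1.24	0.54	0.02	C	0.8	14.1	6.66	0.04
cattle	Gir	BCO2	BCO2.5	2.39	1.01	0.02	G	0.88	17.12	5.40	0.002
cattle	Gir	BCO2	BCO2.9	-1.60	0.74	0.03	A	0.89	17.12	5.40	0.002
cattle	Gir	BCO2	BCO2.10	-3.13	1.20	0.01	C	0.09	17.12	5.40	0.002
cattle	Gir	BCO2	BCO2.12	-1.48	0.90	0.1	C	0.04	17.12	5.40	0.002
cattle	Gir	SCARB1	SCARB1.5	1.28	0.50	0.01	G	0.97	2.56	1.00	0.01
cattle	Sahiwal	BCMO1	BCMO1.8	0.91	0.78	0.25	T	0.32	8.64	3.84	0.03
cattle	Sahiwal	BCMO1	BCMO1.12	-2.48	1.60	0.12	A	0.02	8.64	3.84	0.03
cattle	Sahiwal	BCMO1	BCMO1.14	0.93	0.88	0.29	T	0.30	8.64	3.84	0.03
cattle	Sahiwal	BCO2	BCO2.9	-1.43	1.09	0.19	A	0.92	9.48	3.98	0.02
cattle	Sahiwal	BCO2	BCO2.11	-1.86	1.03	0.07	A	0.06	9.48	3.98	0.02
cattle	Sahiwal	BCO2	BCO2.12	-1.45	0.80	0.07	C	0.24	9.48	3.98	0.02
cattle	Sahiwal	SCARB1	SCARB1.5	-1.67	0.10	0.1	A	0.04	NA	NA	0.02
cattle	Sahiwal	SCARB1	SCARB1.7	-2.00	1.15	0.08	C	0.52	NA	NA	0.02
cattle	Sahiwal	SCARB1	SCARB1.10	-0.58	0.48	0.23	C	0.78	NA	NA	0.02
cattle	Sahiwal	SCARB1	SCARB1.16	-6.21	3.13	0.05	C	0.99	NA	NA	0.02
cattle	Tharparkar	BCMO1	BCMO1.9	0.48	0.39	0.23	C	0.19	0.96	0.78	0.23
cattle	Tharparkar	BCO2	BCO2.1	-0.41	0.31	0.18	G	0.6	0.82	0.62	0.18
buffalo	Combined	BCMO1	BCMO1.21	0.17	0.15	0.25	C	0.58	1.08	0.52	0.04
buffalo	Combined	BCMO1	BCMO1.24	0.37	0.23	0.1	A	0.56	1.08	0.52	0.04
buffalo	Combined	BCO2	BCO2.16	0.45	0.28	0.1	T	0.07	1.62	0.66	0.01
buffalo	Combined	BCO2	BCO2.18	0.38	0.17	0.03	A	0.84	1.62	0.66	0.01
buffalo	Combined	SCARB1	SCARB1.17	0.23	0.16	0.16	T	0.55	1.96	0.66	0.003
buffalo	Combined	SCARB1	SCARB1.19	0.35	0.19	0.06	C	0.46	1.96	0.66	0.003
buffalo	Combined	SCARB1	SCARB1.20	-0.35	0.27	0.2	G	0.72	1.96	0.66	0.003
buffalo	Jafarabadi	BCMO1	BCMO1.21	1.40	0.53	0.008	C	0.62	5.56	1.58	0.0005
buffalo	Jafarabadi	BCMO1	BCMO1.24	1.38	0.78	0.08	A	0.88	5.56	1.58	0.0005
buffalo	Jafarabadi	BCO2	BCO2.14	0.55	0.49	0.26	T	0.43	1.10	0.98	0.26
buffalo	Jafarabadi	SCARB1	SCARB1.19	0.59	0.51	0.24	C	0.54	1.18	1.02	0.24
buffalo	Murrah	BCMO1	BCMO1.22	0.44	0.27	0.1	C	0.47	1.7	0.94	0.07
buffalo	Murrah	BCMO1	BCMO1.24	0.41	0.36	0.25	A	0.84	1.7	0.94	0.07
buffalo	Murrah	SCARB1	SCARB1.22	-2.06	1.11	0.07	C	0.31	8.94	4.44	0.05
buffalo	Murrah	SCARB1	SCARB1.24	2.41	1.12	0.03	A	0.70	8.94	4.44	0.05
buffalo	Pandharpuri	BCMO1	BCMO1.19	-1.83	1.31	0.17	T	0.15	NA	NA	NA
buffalo	Pandharpuri	BCMO1	BCMO1.24	-3.10	2.16	0.16	G	0.04	NA	NA	NA
buffalo	Surti	BCMO1	BCMO1.20	-1.41	1.03	0.17	C	0.92	22.67	11.66	0.05
buffalo	Surti	BCMO1	BCMO1.22	0.85	0.69	0.22	A	0.27	22.67	11.66	0.05
buffalo	Surti	BCMO1	BCMO1.23	9.10	5.43	0.1	A	0.001	22.67	11.66	0.05
buffalo	Surti	BCMO1	BCMO1.24	-1.38	0.84	0.1	G	0.15	22.67	11.66	0.05
buffalo	Surti	BCO2	BCO2.16	2.88	1.17	0.009	T	0.07	6.76	2.38	0.005
buffalo	Surti	SCARB1	SCARB1.20	-2.07	0.88	0.02	G	0.7	4.14	1.76	0.02
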