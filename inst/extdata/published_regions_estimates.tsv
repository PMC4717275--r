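region	locus	cnv_type	size_kb	disc_freq	disc_hr	disc_ci_low	disc_ci_high	disc_p	repl_freq	repl_hr	repl_ci_low	repl_ci_high	repl_p	joint_hr	joint_ci_low	joint_ci_high	joint_p
chr2:18327703-18351537	2p24.2	DUP	23.8	1.3	3.48	1.62	7.45	0.001	1.2	0.85	0.52	1.38	0.512	1.28	0.85	1.94	0.239
chr9:9516348-9526811	9p23	DUP	10.5	1.0	3.30	1.45	7.53	0.005	NA	NA	NA	NA	NA	NA	NA	NA	NA
chr13:32896846-32922331	13q13.1	DEL	25.5	1.3	2.80	1.30	6.03	0.009	NA	NA	NA	NA	NA	NA	NA	NA	NA
chr1:80982632-81056073	1p31.1	DUP	73.4	1.0	2.97	1.29	6.80	0.010	NA	NA	NA	NA	NA	NA	NA	NA	NA
chr6:55828727-55846527	6p12.1	DEL	17.8	3.3	1.83	1.14	2.95	0.012	NA	NA	NA	NA	NA	NA	NA	NA	NA
chr10:13055619-13058458	10p13	DEL	2.8	2.0	2.08	1.17	3.72	0.013	1.2	1.15	0.53	2.47	0.729	1.67	1.05	2.66	0.031
chr6:29855945-29909559	6p22.1	DEL	53.6	11.8	1.38	1.06	1.79	0.015	5.0	0.87	0.55	1.39	0.565	1.24	0.99	1.56	0.057
chr9:73902148-73909871	9q21.12	DUP	7.7	1.8	2.05	1.12	3.75	0.020	4.0	1.31	0.81	2.10	0.272	1.55	1.07	2.25	0.021
chr8:8583109-8589783	8p23.1	DEL	6.7	1.5	2.18	1.12	4.26	0.022	1.0	0.93	0.23	3.75	0.918	1.87	1.02	3.43	0.042
chr8:30990110-31000860	8p12	DEL	10.8	1.0	2.60	1.14	5.94	0.023	NA	NA	NA	NA	NA	NA	NA	NA	NA
chr13:34115595-34143545	13q13.2	DEL	28.0	7.8	1.45	1.05	2.00	0.023	2.6	1.32	0.64	2.70	0.453	1.43	1.07	1.91	0.015
chr15:102028468-102305129	15q26.3	DUP	276.7	1.0	2.52	1.12	5.69	0.026	NA	NA	NA	NA	NA	NA	NA	NA	NA
chr20:36051525-42681088	20q11.23;20q12;20q13.11;20q13.12	DEL	6629.6	1.8	0.45	0.22	0.91	0.026	1.0	0.89	0.47	1.70	0.729	0.65	0.40	1.05	0.079
chr7:118006251-118070496	7q31.31	DEL	64.2	1.0	2.69	1.11	6.56	0.029	NA	NA	NA	NA	NA	NA	NA	NA	NA
chr6:31275246-31285292	6p21.33	DEL	10.0	2.8	1.76	1.05	2.96	0.032	2.4	1.02	0.67	1.56	0.923	1.27	0.92	1.74	0.150
chr13:88960710-89033066	13q31.2	DEL	72.4	1.0	2.38	1.06	5.37	0.036	NA	NA	NA	NA	NA	NA	NA	NA	NA
chr22:18844632-19016663	22q11.21	DUP	172.0	1.3	2.11	1.04	4.28	0.039	NA	NA	NA	NA	NA	NA	NA	NA	NA
chr1:161490896-161617516	1q23.3	DUP	126.6	1.8	0.48	0.23	0.98	0.043	1.4	2.60	1.35	5.04	0.004	1.17	0.72	1.90	0.520
chr6:77439969-77448731	6q14.1	DEL	8.8	6.5	1.42	1.01	2.00	0.046	4.4	1.27	0.88	1.84	0.194	1.35	1.04	1.74	0.023
chr13:82081150-82087510	13q31.1	DEL	6.4	1.0	2.28	1.01	5.14	0.048	NA	NA	NA	NA	NA	NA	NA	NA	NA
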