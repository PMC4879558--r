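Region	Species	Size	A	G	T	C	AT	ATskew	GCskew
whole_genome	E_narcissus	15376	40.78	7.68	40.21	11.33	80.99	0.007	-0.192
whole_genome	H_armigera	15347	40.54	7.69	40.43	11.34	80.97	0.001	-0.192
whole_genome	O_lunifer	15593	40.09	7.56	37.75	14.60	77.84	0.030	-0.318
whole_genome	P_flavescens	15659	40.07	7.87	40.80	11.26	80.87	-0.009	-0.177
whole_genome	B_mandarina	15682	43.11	7.40	38.48	11.01	81.59	0.057	-0.196
whole_genome	A_selene	15236	38.54	8.05	40.37	13.03	78.91	-0.023	-0.236
whole_genome	M_sexta	15516	40.67	7.46	41.11	10.76	81.79	-0.005	-0.181
PCG	E_narcissus	11190	40.68	8.40	37.72	13.20	78.42	0.038	-0.222
PCG	H_armigera	11203	34.25	10.62	45.18	9.95	79.43	-0.138	0.033
PCG	O_lunifer	11266	32.47	12.08	43.26	12.19	75.73	-0.142	-0.004
PCG	P_flavescens	11206	39.40	8.90	39.56	12.15	78.96	-0.002	-0.154
PCG	B_mandarina	11196	42.83	8.26	37.04	11.87	79.87	0.072	-0.179
PCG	A_selene	11231	37.93	8.74	39.44	13.89	77.37	-0.020	-0.228
PCG	M_sexta	11178	40.40	8.22	39.89	11.49	80.29	0.006	-0.166
tRNA	E_narcissus	1450	41.52	8.00	40.48	10.00	82.00	0.013	-0.111
tRNA	H_armigera	1473	41.41	8.15	40.39	10.05	81.81	0.012	-0.104
tRNA	O_lunifer	1666	41.78	7.32	39.86	11.04	81.63	0.023	-0.202
tRNA	P_flavescens	1474	41.66	7.80	40.64	9.91	82.29	0.012	-0.119
tRNA	B_mandarina	1472	41.78	7.81	39.95	10.46	81.73	0.022	-0.145
tRNA	A_selene	1459	40.37	8.16	40.23	11.24	80.60	0.002	-0.159
tRNA	M_sexta	1470	41.09	8.16	40.68	10.07	81.77	0.005	-0.145
rRNA	E_narcissus	2122	41.89	5.00	42.60	10.51	84.50	-0.008	-0.355
rRNA	H_armigera	2189	41.75	4.89	43.40	9.96	85.15	-0.019	-0.341
rRNA	O_lunifer	2157	41.96	4.82	40.19	13.03	82.15	0.022	-0.460
rRNA	P_flavescens	2198	41.31	4.73	44.04	9.92	85.35	-0.032	-0.354
rRNA	B_mandarina	2134	43.86	4.78	41.05	10.31	84.91	0.028	-0.366
rRNA	A_selene	2126	39.93	4.99	43.79	11.29	83.73	-0.046	-0.387
rRNA	M_sexta	2168	41.37	4.84	44.05	9.73	85.42	-0.031	-0.335
control_region	E_narcissus	434	47.47	1.15	49.08	2.30	96.54	-0.017	-0.332
control_region	H_armigera	328	44.51	1.22	50.61	3.66	95.12	-0.064	-0.500
control_region	O_lunifer	319	44.5	1.6	48.9	5.0	93.4	-0.047	-0.524
control_region	P_flavescens	541	42.14	2.22	49.72	5.91	91.87	-0.083	-0.454
control_region	B_mandarina	484	46.49	2.69	47.93	2.89	94.42	-0.015	-0.036
control_region	A_selene	339	43.07	5.90	44.84	6.19	87.91	-0.020	-0.024
control_region	M_sexta	324	45.06	1.54	50.31	3.09	95.37	-0.055	-0.419
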