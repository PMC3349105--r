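compound_id	E_T	E_b	dHf	mu	eps_HOMO	eps_LUMO	A_S	V_m	E_H	logP	R_m	alpha	M_W	Q_N	logD	pKa	PSA	HD	HA
1	−95473.52	−4458.85	−114.42	5.42	−9.22	−0.81	363.12	299.49	−5.38	−1.56	91.23	31.51	328.43	−0.28	−1.48	9.66	84.09	1	6
2	−102871.32	−5376.37	66.71	1.30	−7.68	−0.88	390.65	362.08	−7.20	−0.06	125.84	44.97	400.97	−0.26	5.06	3.40	52.01	1	3
3	−130832.64	−5768.48	−126.83	3.34	−8.19	−0.61	428.40	375.93	−7.16	0.73	126.33	44.61	434.52	−0.26	4.42	3.40	52.01	1	3
4	−121985.47	−5378.24	−77.03	3.37	−7.75	−0.54	397.66	353.23	−1.07	−0.19	119.66	41.84	407.50	−0.24	4.21	8.21	35.02	0	3
5	−86841.85	−4443.93	103.02	4.27	−8.12	−0.37	332.90	297.11	−2.85	−0.73	103.53	36.47	326.83	−0.26	3.28	7.14	30.87	1	4
6	−121479.92	−5930.86	−3.63	2.83	−8.88	−0.67	417.97	374.26	−3.95	0.63	118.48	43.54	410.49	−0.25	2.27	7.89	61.94	0	6
7	−80076.44	−4363.58	101.99	2.47	−8.20	−0.46	534.03	908.51	−2.75	−0.27	100.06	35.90	312.43	−0.26	2.68	6.08	59.11	1	4
8	−80841.49	−4306.45	−14.17	5.20	−8.83	−0.15	306.24	268.61	−4.73	−0.38	85.35	31.53	284.36	−0.22	1.07	10.00	45.33	1	4
9	−73412.66	−4717.17	78.67	0.93	−8.52	−0.23	320.59	290.43	−1.14	1.77	102.76	36.03	287.40	−0.24	4.86	8.95	3.24	0	1
10	−102872.02	−4942.24	104.46	3.65	−8.49	−0.53	386.68	336.51	−3.39	0.40	109.91	39.94	371.87	−0.25	1.58	6.73	42.39	0	6
11	−69008.06	−4266.06	78.00	1.69	−8.56	0.46	294.12	264.06	−0.67	0.94	91.21	32.26	264.37	−0.25	2.76	8.26	6.48	0	2
12	−72005.62	−4460.87	59.58	0.52	−8.66	0.06	315.58	285.55	−0.79	0.50	99.09	35.74	295.44	−0.26	4.49	9.04	31.48	0	1
13	−70511.88	−4151.08	82.98	1.40	−8.71	0.13	289.58	259.66	−1.56	1.16	87.08	31.55	265.36	−0.25	1.97	8.10	19.37	0	3
14	−110495.96	−5922.35	−34.38	4.11	−8.77	0.13	427.84	371.81	−1.85	1.18	109.35	42.11	385.51	−0.26	3.35	6.73	69.64	0	7
15	−81555.82	−4027.14	−16.02	2.30	−8.35	−0.50	327.29	270.64	−7.57	−1.53	85.92	29.34	295.40	−0.27	−1.38	9.49	73.58	2	5
16	−74102.91	−3978.93	139.36	5.47	−8.54	0.05	312.82	264.07	−6.38	−1.31	87.27	31.13	269.35	−0.27	−1.10	9.49	44.81	1	5
17	−82988.15	−4308.72	−22.22	6.51	−8.49	0.00	320.46	275.04	−6.13	−1.01	86.03	31.82	287.36	−0.28	−0.44	9.52	57.36	2	5
18	−140797.97	−6228.62	−162.08	3.89	−8.76	−0.11	480.40	412.47	−8.51	2.25	122.44	47.39	465.95	−0.27	2.60	7.77	86.05	3	7
19	−50258.52	−2618.46	1.22	3.41	−8.31	0.14	204.41	168.41	−15.76	−2.21	56.33	20.15	176.22	−0.35	−2.20	10.31	62.04	4	3
20	−73460.18	−4116.22	−55.72	2.21	−8.77	−0.51	311.49	260.89	−7.25	0.68	83.38	30.25	259.35	−0.30	1.37	9.14	41.49	2	3
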