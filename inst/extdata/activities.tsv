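compound_id	name	pKi	pD2	pA2
1	Tiapride	—	7.97	5.10
2	Clopenthixol	7.60	7.99	7.30
3	Flupentixol	7.00	7.88	6.90
4	Trifluoperazine	7.90	8.04	5.70
5	Clozapine	6.00	—	7.50
6	Risperidone	9.90	8.16	6.69
7	Olanzapine	8.10	8.10	7.20
8	Tropisetron	8.40	—	6.60
9	Cyproheptadine	8.22	—	8.73
10	Trazodone	7.40	—	8.79
11	Mianserin	9.70	8.09	7.50
12	Pizotifen	7.40	—	9.20
13	Mirtazapine	8.40	6.88	7.99
14	Buspirone	7.70	7.70	6.35
15	Sumatriptan	6.60	5.80	—
16	Rizatriptan	6.40	6.30	—
17	Zolmitriptan	6.60	6.20	—
18	Cisapride	7.40	7.60	7.30
19	Serotonin	6.40	—	—
20	Propranolol	7.50	—	6.08
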