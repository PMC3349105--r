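compound_id	C	S1	S2	S3	S4	S5	S6	S7
1	−0.140	−0.167	−0.131	−0.176	−0.185	−0.176	−0.105	−0.140
2	0.026	0.026	0.140	0.043	0.078	0.087	0.105	0.087
3	0.043	0.043	0.131	0.043	0.087	0.078	0.096	0.096
4	0.308	0.308	0.389	0.298	0.317	0.308	0.368	0.327
5	−0.026	−0.035	0.035	0.000	0.009	−0.009	0.035	0.009
6	−0.259	−0.269	−0.231	−0.317	−0.269	−0.368	−0.250	−0.240
7	0.078	0.087	0.176	0.078	0.096	0.096	0.149	0.140
8	0.122	0.105	0.149	0.061	0.061	0.000	0.131	0.105
9	0.269	0.259	0.288	0.222	0.240	0.231	0.278	0.259
10	−0.466	−0.466	−0.410	−0.410	−0.389	−0.421	−0.389	−0.368
11	−0.035	−0.035	0.000	−0.035	−0.026	−0.009	0.000	0.017
12	0.269	0.278	0.308	0.250	0.231	0.222	0.288	0.327
13	−0.122	−0.122	−0.061	−0.122	−0.122	−0.087	−0.070	−0.070
14	−0.337	−0.337	−0.231	−0.337	−0.317	−0.317	−0.269	−0.269
15	−0.078	−0.140	−0.070	−0.176	−0.222	−0.158	−0.122	−0.140
16	0.194	0.203	0.399	0.213	0.140	0.259	0.240	0.231
17	−0.078	−0.096	0.017	−0.114	−0.167	−0.070	−0.035	−0.105
18	−0.240	−0.231	−0.105	−0.213	−0.222	−0.213	−0.185	−0.185
19	0.087	0.087	0.194	0.035	0.017	−0.026	0.140	0.087
20	0.105	0.105	0.176	0.078	0.043	0.026	0.114	0.096
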