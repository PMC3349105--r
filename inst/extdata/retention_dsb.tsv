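compound_id	C	S1	S2	S3	S4	S5	S6	S7
1	0.009	0.009	0.035	−0.035	−0.026	0.026	0.026	0.009
2	0.269	0.259	0.259	0.213	0.222	0.278	0.250	0.222
3	0.250	0.259	0.240	0.194	0.213	0.278	0.231	0.185
4	0.513	0.489	0.477	0.454	0.466	0.501	0.466	0.432
5	0.194	0.194	0.149	0.122	0.140	0.203	0.149	0.105
6	0.070	0.052	0.043	0.000	0.035	0.061	0.026	−0.017
7	0.327	0.368	0.347	0.259	0.288	0.288	0.308	0.259
8	0.131	0.096	0.131	0.070	0.114	0.087	0.131	0.096
9	0.410	0.378	0.389	0.317	0.358	0.410	0.368	0.347
10	−0.250	−0.250	−0.308	−0.389	−0.317	−0.231	−0.288	−0.368
11	0.203	0.194	0.185	0.122	0.158	0.122	0.158	0.105
12	0.489	0.432	0.149	0.368	0.347	0.466	0.389	0.378
13	0.149	0.149	0.131	0.078	0.096	0.158	0.114	0.078
14	−0.009	0.026	−0.043	−0.140	−0.087	0.009	−0.017	−0.017
15	−0.009	−0.035	−0.017	−0.070	−0.070	−0.026	−0.026	−0.078
16	0.278	0.308	0.317	0.240	0.231	0.298	0.278	0.240
17	0.017	0.000	0.043	−0.035	−0.026	0.035	0.026	−0.026
18	0.122	0.140	0.105	0.035	0.061	0.131	0.096	0.061
19	0.203	0.222	0.231	0.149	0.140	0.176	0.194	0.149
20	0.203	0.222	0.185	0.114	0.131	0.176	0.203	0.158
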