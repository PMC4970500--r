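# N Z=7 f1 f2 vs photon energy (eV); Cromer-Liberman, f1 = Z + f'
E(eV)	f1	f2
250.00	5.105512	0.391839
258.76	5.065033	0.374032
267.83	5.019249	0.356966
277.21	4.967115	0.340609
286.93	4.907267	0.324934
296.98	4.837890	0.309913
307.39	4.756507	0.295519
318.16	4.659648	0.281729
329.31	4.542275	0.268517
340.85	4.396766	0.255861
352.79	4.210970	0.243739
365.16	3.964164	0.232130
377.95	3.617718	0.221014
391.20	3.089990	0.210372
404.91	1.362698	4.045291
419.09	3.564597	3.878906
433.78	4.408683	3.716672
448.98	4.950525	3.558642
464.71	5.349572	3.404859
481.00	5.663122	3.255356
497.85	5.922577	3.110111
515.30	6.135530	2.969048
533.36	6.315915	2.832337
552.05	6.470303	2.699970
571.39	6.603368	2.571927
591.42	6.718580	2.448184
612.14	6.818605	2.328708
633.59	6.905545	2.213457
655.79	6.981101	2.102386
678.78	7.068829	1.995426
702.56	7.123435	1.889096
727.18	7.169269	1.787771
752.66	7.208158	1.691254
779.04	7.240960	1.599355
806.34	7.268411	1.511890
834.59	7.291148	1.428678
863.84	7.309726	1.349546
894.11	7.324633	1.274324
925.44	7.336296	1.202849
957.87	7.345096	1.134962
991.44	7.351367	1.070509
1026.18	7.355352	1.008846
1062.14	7.357252	0.950306
1099.36	7.357351	0.894918
1137.88	7.355897	0.842525
1177.76	7.353106	0.792982
1219.03	7.349168	0.746147
1261.75	7.344250	0.701884
1305.96	7.338500	0.660066
1351.73	7.332049	0.620568
1399.09	7.325013	0.583272
1448.12	7.317496	0.548067
1498.87	7.309588	0.514845
1551.39	7.301370	0.483503
1605.76	7.292887	0.453944
1662.03	7.286299	0.425887
1720.27	7.277317	0.399472
1780.55	7.268278	0.374611
1842.94	7.259229	0.351219
1907.52	7.250208	0.329214
1974.37	7.241250	0.308518
2043.56	7.232385	0.289059
2115.17	7.223637	0.270766
2189.29	7.215029	0.253574
2266.01	7.206579	0.237420
2345.41	7.198302	0.222245
2427.60	7.190211	0.207994
2512.67	7.182316	0.194613
2600.72	7.174625	0.182051
2691.85	7.167145	0.170263
2786.18	7.159880	0.159201
2883.82	7.152834	0.148825
2984.87	7.146009	0.139094
3089.47	7.139401	0.129917
3197.73	7.133008	0.121313
3309.79	7.126831	0.113258
3425.77	7.120869	0.105718
3545.82	7.115121	0.098661
3670.07	7.109586	0.092058
3798.68	7.104260	0.085881
3931.80	7.099141	0.080102
4069.58	7.094224	0.074699
4212.18	7.089509	0.069647
4359.79	7.084984	0.064924
4512.57	7.080647	0.060510
4670.70	7.076493	0.056386
4834.37	7.072519	0.052532
5003.78	7.068717	0.048933
5179.12	7.065083	0.045572
5360.61	7.061611	0.042434
5548.46	7.058296	0.039504
5742.89	7.055132	0.036770
5944.14	7.052114	0.034218
6152.43	7.049237	0.031837
6368.03	7.046495	0.029617
6591.18	7.043883	0.027546
6822.15	7.041396	0.025615
7061.22	7.039029	0.023815
7308.66	7.036777	0.022137
7564.77	7.034676	0.020573
7829.86	7.032630	0.019115
8104.23	7.030686	0.017758
8388.23	7.028840	0.016494
8682.17	7.027088	0.015319
8986.41	7.025438	0.014221
9301.32	7.023892	0.013192
9627.26	7.022412	0.012236
9964.62	7.021000	0.011349
10313.81	7.019658	0.010525
10675.23	7.018383	0.009760
11049.31	7.017174	0.009050
11436.51	7.016028	0.008391
11837.27	7.014943	0.007779
12252.08	7.013917	0.007211
12681.42	7.012944	0.006684
13125.80	7.012025	0.006196
13585.76	7.011156	0.005742
14061.84	7.010334	0.005321
14554.60	7.009558	0.004931
15064.63	7.008825	0.004569
15592.53	7.008133	0.004233
16138.93	7.007480	0.003921
16704.48	7.006863	0.003633
17289.84	7.006282	0.003365
17895.72	7.005733	0.003116
18522.83	7.005216	0.002886
19171.91	7.004728	0.002673
19843.74	7.004269	0.002475
20539.12	7.003835	0.002291
21258.86	7.003427	0.002121
22003.82	7.003043	0.001964
22774.88	7.002680	0.001818
23572.97	7.002339	0.001682
24399.02	7.002018	0.001557
25254.02	7.001716	0.001441
26138.98	7.001431	0.001333
27054.96	7.001163	0.001233
28003.03	7.000911	0.001140
28984.32	7.000674	0.001053
30000.00	7.000451	0.000974
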