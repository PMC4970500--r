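# P Z=15 f1 f2 vs photon energy (eV); Cromer-Liberman, f1 = Z + f'
E(eV)	f1	f2
250.00	11.361934	8.944822
258.76	11.678291	8.626505
267.83	11.965951	8.314836
277.21	12.228683	8.009889
286.93	12.467300	7.711758
296.98	12.684748	7.420527
307.39	12.882840	7.136248
318.16	13.063174	6.858957
329.31	13.272996	6.582031
340.85	13.419101	6.311627
352.79	13.550474	6.049066
365.16	13.668277	5.794328
377.95	13.773562	5.547376
391.20	13.867286	5.308161
404.91	13.950324	5.076618
419.09	14.023482	4.852675
433.78	14.087501	4.636242
448.98	14.143068	4.427225
464.71	14.190816	4.225516
481.00	14.231333	4.031001
497.85	14.265168	3.843555
515.30	14.292828	3.663048
533.36	14.366952	3.488108
552.05	14.378123	3.316785
571.39	14.384583	3.152960
591.42	14.386794	2.996359
612.14	14.385150	2.846714
633.59	14.380010	2.703762
655.79	14.371690	2.567249
678.78	14.360475	2.436927
702.56	14.346619	2.312555
727.18	14.330345	2.193898
752.66	14.311849	2.080730
779.04	14.295359	1.972512
806.34	14.272231	1.869396
834.59	14.247332	1.771245
863.84	14.220767	1.677847
894.11	14.192617	1.589000
925.44	14.162936	1.504506
957.87	14.131751	1.424175
991.44	14.099063	1.347825
1026.18	14.065095	1.274575
1062.14	14.029424	1.204870
1099.36	13.991906	1.138784
1137.88	13.952453	1.076140
1177.76	13.910914	1.016770
1219.03	13.867074	0.960515
1261.75	13.820642	0.907221
1305.96	13.771232	0.856741
1351.73	13.718348	0.808935
1399.09	13.661344	0.763669
1448.12	13.599379	0.720817
1498.87	13.531347	0.680255
1551.39	13.455762	0.641868
1605.76	13.370587	0.605546
1662.03	13.272946	0.571183
1720.27	13.158617	0.538679
1780.55	13.021081	0.507937
1842.94	12.849579	0.478867
1907.52	12.624562	0.451383
1974.37	12.304927	0.425402
2043.56	11.778839	0.400845
2115.17	10.459096	0.377638
2189.29	11.089225	4.027101
2266.01	12.483141	3.858633
2345.41	13.165336	3.652492
2427.60	13.619825	3.457235
2512.67	13.955072	3.272283
2600.72	14.214511	3.097099
2691.85	14.421954	2.931194
2786.18	14.591134	2.774080
2883.82	14.729669	2.625788
2984.87	14.847857	2.484524
3089.47	14.947550	2.349547
3197.73	15.031153	2.221092
3309.79	15.101362	2.098968
3425.77	15.160292	1.982901
3545.82	15.209624	1.872631
3670.07	15.252491	1.767819
3798.68	15.286320	1.668316
3931.80	15.314001	1.573894
4069.58	15.336343	1.484324
4212.18	15.354037	1.399387
4359.79	15.372602	1.318440
4512.57	15.382174	1.241351
4670.70	15.388614	1.168459
4834.37	15.392345	1.099554
5003.78	15.393734	1.034437
5179.12	15.393103	0.972916
5360.61	15.390733	0.914809
5548.46	15.386872	0.859942
5742.89	15.381737	0.808149
5944.14	15.375521	0.759271
6152.43	15.368394	0.713158
6368.03	15.360507	0.669665
6591.18	15.352069	0.628654
6822.15	15.343030	0.589994
7061.22	15.333589	0.553563
7308.66	15.323836	0.519240
7564.77	15.313850	0.486914
7829.86	15.303704	0.456477
8104.23	15.293460	0.427826
8388.23	15.283173	0.400865
8682.17	15.272892	0.375501
8986.41	15.262636	0.351631
9301.32	15.254569	0.329165
9627.26	15.244253	0.307871
9964.62	15.234107	0.287909
10313.81	15.224140	0.269199
10675.23	15.214374	0.251663
11049.31	15.204828	0.235232
11436.51	15.195517	0.219838
11837.27	15.186453	0.205418
12252.08	15.177644	0.191913
12681.42	15.169098	0.179267
13125.80	15.160818	0.167427
13585.76	15.152807	0.156343
14061.84	15.145065	0.145970
14554.60	15.137593	0.136262
15064.63	15.130389	0.127179
15592.53	15.123450	0.118682
16138.93	15.116773	0.110735
16704.48	15.110354	0.103303
17289.84	15.104187	0.096354
17895.72	15.098268	0.089857
18522.83	15.092591	0.083785
19171.91	15.087150	0.078110
19843.74	15.081938	0.072808
20539.12	15.076950	0.067854
21258.86	15.072178	0.063227
22003.82	15.067615	0.058905
22774.88	15.063256	0.054870
23572.97	15.059093	0.051103
24399.02	15.055119	0.047587
25254.02	15.051328	0.044305
26138.98	15.047713	0.041243
27054.96	15.044259	0.038377
28003.03	15.040956	0.035694
28984.32	15.037812	0.033195
30000.00	15.034819	0.030867
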