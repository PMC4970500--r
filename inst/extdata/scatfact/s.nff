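# S Z=16 f1 f2 vs photon energy (eV); Cromer-Liberman, f1 = Z + f'
E(eV)	f1	f2
250.00	9.784168	11.070837
258.76	10.385069	10.755408
267.83	10.916256	10.438159
277.21	11.394037	10.119841
286.93	12.121269	9.757469
296.98	12.491335	9.396157
307.39	12.824478	9.043394
318.16	13.125162	8.699229
329.31	13.397003	8.363695
340.85	13.644136	8.036759
352.79	13.866588	7.718460
365.16	14.067786	7.408800
377.95	14.249602	7.107750
391.20	14.457447	6.813090
404.91	14.603031	6.522064
419.09	14.732885	6.240283
433.78	14.848327	5.967656
448.98	14.950547	5.704083
464.71	15.040625	5.449445
481.00	15.119542	5.203618
497.85	15.188194	4.966464
515.30	15.247403	4.737837
533.36	15.297925	4.517581
552.05	15.340456	4.305534
571.39	15.375637	4.101527
591.42	15.404061	3.905383
612.14	15.426273	3.716923
633.59	15.442779	3.535960
655.79	15.454009	3.362307
678.78	15.486964	3.193645
702.56	15.485215	3.032197
727.18	15.479654	2.878101
752.66	15.470644	2.731070
779.04	15.458512	2.590826
806.34	15.443548	2.457097
834.59	15.426007	2.329620
863.84	15.406115	2.208141
894.11	15.384068	2.092412
925.44	15.361076	1.982168
957.87	15.334718	1.877190
991.44	15.306657	1.777354
1026.18	15.278396	1.681426
1062.14	15.248093	1.590065
1099.36	15.215709	1.503403
1137.88	15.181514	1.421216
1177.76	15.145622	1.343290
1219.03	15.108061	1.269418
1261.75	15.068796	1.199405
1305.96	15.027734	1.133061
1351.73	14.984727	1.070206
1399.09	14.939565	1.010669
1448.12	14.891962	0.954285
1498.87	14.841550	0.900896
1551.39	14.787849	0.850352
1605.76	14.730240	0.802511
1662.03	14.667916	0.757235
1720.27	14.599819	0.714394
1780.55	14.524533	0.673865
1842.94	14.440124	0.635528
1907.52	14.343869	0.599272
1974.37	14.231792	0.564988
2043.56	14.097795	0.532575
2115.17	13.931899	0.501935
2189.29	13.716202	0.472976
2266.01	13.413804	0.445610
2345.41	12.928049	0.419754
2427.60	11.811834	0.395328
2512.67	11.913439	4.025373
2600.72	13.441661	3.842023
2691.85	14.151108	3.636134
2786.18	14.614807	3.441584
2883.82	14.953171	3.257734
2984.87	15.214143	3.083981
3089.47	15.423471	2.920344
3197.73	15.596630	2.764479
3309.79	15.739057	2.615658
3425.77	15.856687	2.473967
3545.82	15.955311	2.339168
3670.07	16.038110	2.210968
3798.68	16.107541	2.089092
3931.80	16.165778	1.973269
4069.58	16.214468	1.863238
4212.18	16.254960	1.758747
4359.79	16.289826	1.659525
4512.57	16.316982	1.565327
4670.70	16.338825	1.475979
4834.37	16.356044	1.391262
5003.78	16.373332	1.310692
5179.12	16.382528	1.233951
5360.61	16.388622	1.161391
5548.46	16.392037	1.092804
5742.89	16.393137	1.027990
5944.14	16.392241	0.966760
6152.43	16.389627	0.908930
6368.03	16.385542	0.854328
6591.18	16.380202	0.802789
6822.15	16.373798	0.754154
7061.22	16.366499	0.708272
7308.66	16.358455	0.665001
7564.77	16.349796	0.624203
7829.86	16.340640	0.585748
8104.23	16.331109	0.549511
8388.23	16.321248	0.515375
8682.17	16.311161	0.483227
8986.41	16.300911	0.452927
9301.32	16.290520	0.424348
9627.26	16.280081	0.397489
9964.62	16.269650	0.372252
10313.81	16.259276	0.348544
10675.23	16.249004	0.326278
11049.31	16.240484	0.305218
11436.51	16.230330	0.285452
11837.27	16.220361	0.266922
12252.08	16.210600	0.249553
12681.42	16.201064	0.233274
13125.80	16.191766	0.218021
13585.76	16.182718	0.203731
14061.84	16.173929	0.190345
14554.60	16.165402	0.177809
15064.63	16.157144	0.166070
15592.53	16.149155	0.155080
16138.93	16.141437	0.144792
16704.48	16.133988	0.135164
17289.84	16.126807	0.126155
17895.72	16.119892	0.117726
18522.83	16.113238	0.109841
19171.91	16.106841	0.102467
19843.74	16.100696	0.095572
20539.12	16.094799	0.089125
21258.86	16.089143	0.083099
22003.82	16.083722	0.077467
22774.88	16.078530	0.072204
23572.97	16.073561	0.067287
24399.02	16.068807	0.062695
25254.02	16.064262	0.058405
26138.98	16.059920	0.054400
27054.96	16.055766	0.050650
28003.03	16.051788	0.047135
28984.32	16.047994	0.043860
30000.00	16.044375	0.040807
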