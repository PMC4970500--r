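# K Z=19 f1 f2 vs photon energy (eV); Cromer-Liberman, f1 = Z + f'
E(eV)	f1	f2
250.00	5.056771	1.445877
258.76	4.377915	1.415820
267.83	3.463937	1.385080
277.21	2.167991	1.353733
286.93	0.179603	1.321852
296.98	-7.125566	15.457913
307.39	1.829564	14.931126
318.16	4.908790	14.409670
329.31	6.866029	13.894257
340.85	8.414744	13.381606
352.79	9.471510	12.874005
365.16	10.247182	12.375212
377.95	9.666191	13.427674
391.20	11.795046	12.937530
404.91	12.782040	12.456363
419.09	13.558222	11.984564
433.78	14.212059	11.522486
448.98	14.777623	11.070444
464.71	15.273462	10.628713
481.00	15.711537	10.197533
497.85	16.173859	9.775856
515.30	16.548666	9.349844
533.36	16.845765	8.937244
552.05	17.108583	8.538933
571.39	17.341044	8.154649
591.42	17.546459	7.784115
612.14	17.727664	7.427051
633.59	17.887122	7.083165
655.79	18.035798	6.751000
678.78	18.156971	6.431438
702.56	18.262020	6.124418
727.18	18.352484	5.829616
752.66	18.429741	5.546707
779.04	18.495030	5.275362
806.34	18.549468	5.015252
834.59	18.594066	4.766048
863.84	18.629739	4.527420
894.11	18.657321	4.299041
925.44	18.677567	4.080584
957.87	18.691164	3.871727
991.44	18.698739	3.672149
1026.18	18.699527	3.480393
1062.14	18.694915	3.297398
1099.36	18.685873	3.123239
1137.88	18.672879	2.957543
1177.76	18.664926	2.799881
1219.03	18.648860	2.648970
1261.75	18.625115	2.505622
1305.96	18.598874	2.369567
1351.73	18.570393	2.240463
1399.09	18.539892	2.117984
1448.12	18.507554	2.001815
1498.87	18.473519	1.891657
1551.39	18.442120	1.786896
1605.76	18.404668	1.687569
1662.03	18.365770	1.593487
1720.27	18.325444	1.504392
1780.55	18.283673	1.420036
1842.94	18.240401	1.340184
1907.52	18.195527	1.264610
1974.37	18.148903	1.193100
2043.56	18.100324	1.125448
2115.17	18.049515	1.061457
2189.29	17.996119	1.000941
2266.01	17.939675	0.943722
2345.41	17.879583	0.889630
2427.60	17.815065	0.838502
2512.67	17.745095	0.790184
2600.72	17.668303	0.744530
2691.85	17.582812	0.701401
2786.18	17.485978	0.660663
2883.82	17.373935	0.622189
2984.87	17.240745	0.585861
3089.47	17.076553	0.551280
3197.73	16.863913	0.518635
3309.79	16.566523	0.487869
3425.77	16.088202	0.458877
3545.82	14.969233	0.431558
3670.07	15.214615	3.951950
3798.68	16.606463	3.734598
3931.80	17.278207	3.538388
4069.58	17.720349	3.351363
4212.18	18.044358	3.173155
4359.79	18.294870	3.003410
4512.57	18.494677	2.841785
4670.70	18.657174	2.687947
4834.37	18.790777	2.541641
5003.78	18.901907	2.402478
5179.12	18.994603	2.270148
5360.61	19.072082	2.144364
5548.46	19.137309	2.024840
5742.89	19.191470	1.911286
5944.14	19.236206	1.803476
6152.43	19.273097	1.701158
6368.03	19.303229	1.604088
6591.18	19.327517	1.512031
6822.15	19.346737	1.424760
7061.22	19.361551	1.342057
7308.66	19.374214	1.263601
7564.77	19.381494	1.189230
7829.86	19.385894	1.118924
8104.23	19.387829	1.052481
8388.23	19.387588	0.989707
8682.17	19.385502	0.930417
8986.41	19.381952	0.874301
9301.32	19.377179	0.821052
9627.26	19.371074	0.770876
9964.62	19.363889	0.723608
10313.81	19.355830	0.679089
10675.23	19.347065	0.637168
11049.31	19.337738	0.597702
11436.51	19.327972	0.560556
11837.27	19.317872	0.525602
12252.08	19.307531	0.492717
12681.42	19.297026	0.461787
13125.80	19.286428	0.432701
13585.76	19.275795	0.405357
14061.84	19.265179	0.379655
14554.60	19.254624	0.355503
15064.63	19.244169	0.332812
15592.53	19.233859	0.311498
16138.93	19.224881	0.291369
16704.48	19.214746	0.272485
17289.84	19.204822	0.254783
17895.72	19.195125	0.238190
18522.83	19.185671	0.222640
19171.91	19.176469	0.208070
19843.74	19.167530	0.194420
20539.12	19.158858	0.181635
21258.86	19.150457	0.169661
22003.82	19.142330	0.158450
22774.88	19.134478	0.147955
23572.97	19.126899	0.138131
24399.02	19.119593	0.128937
25254.02	19.112555	0.120334
26138.98	19.105783	0.112286
27054.96	19.099279	0.104710
28003.03	19.093028	0.097559
28984.32	19.087013	0.090889
30000.00	19.081233	0.084667
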