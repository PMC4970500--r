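# Mn Z=25 f1 f2 vs photon energy (eV); Cromer-Liberman, f1 = Z + f'
E(eV)	f1	f2
250.00	14.875045	4.191111
258.76	14.919033	4.089012
267.83	14.956790	3.988182
277.21	14.988007	3.888582
286.93	15.012315	3.790178
296.98	15.029276	3.692944
307.39	15.038376	3.596857
318.16	15.039008	3.501900
329.31	15.030456	3.408061
340.85	15.035318	3.314328
352.79	15.004691	3.220627
365.16	14.961697	3.128232
377.95	14.904909	3.037143
391.20	14.832579	2.947364
404.91	14.742556	2.858900
419.09	14.632156	2.771761
433.78	14.497987	2.685958
448.98	14.335699	2.601503
464.71	14.139601	2.518410
481.00	13.902096	2.436696
497.85	13.612776	2.356378
515.30	13.256949	2.277472
533.36	12.813104	2.199997
552.05	12.248302	2.123972
571.39	11.509162	2.049413
591.42	10.502562	1.976339
612.14	9.049006	1.904768
633.59	6.748906	1.834714
655.79	4.340776	16.014852
678.78	10.408531	15.274074
702.56	13.068453	14.560441
727.18	14.747650	13.873358
752.66	15.855498	13.212219
779.04	16.437782	14.319996
806.34	18.097005	13.687682
834.59	19.181782	13.078293
863.84	20.037797	12.491257
894.11	20.746559	11.926003
925.44	21.352135	11.381845
957.87	21.863853	10.858351
991.44	22.305817	10.355184
1026.18	22.695244	9.870735
1062.14	23.033952	9.404618
1099.36	23.363730	8.953802
1137.88	23.634798	8.515087
1177.76	23.851503	8.095119
1219.03	24.038544	7.693389
1261.75	24.199510	7.309258
1305.96	24.346862	6.941868
1351.73	24.463842	6.589557
1399.09	24.562539	6.253211
1448.12	24.644980	5.932235
1498.87	24.712944	5.626045
1551.39	24.767998	5.334074
1605.76	24.810882	5.055788
1662.03	24.844193	4.790637
1720.27	24.868326	4.538083
1780.55	24.884263	4.297614
1842.94	24.892885	4.068735
1907.52	24.894978	3.850966
1974.37	24.891248	3.643840
2043.56	24.882324	3.446907
2115.17	24.868770	3.259728
2189.29	24.851089	3.081882
2266.01	24.829725	2.912958
2345.41	24.805075	2.752563
2427.60	24.777486	2.600315
2512.67	24.747262	2.455847
2600.72	24.716161	2.318741
2691.85	24.681621	2.188642
2786.18	24.644275	2.065411
2883.82	24.605185	1.948715
2984.87	24.564462	1.838230
3089.47	24.527504	1.732848
3197.73	24.483760	1.632819
3309.79	24.438291	1.538374
3425.77	24.390835	1.449211
3545.82	24.341598	1.365050
3670.07	24.290485	1.285621
3798.68	24.237319	1.210669
3931.80	24.181832	1.139949
4069.58	24.123653	1.073233
4212.18	24.062282	1.010301
4359.79	23.997054	0.950945
4512.57	23.927089	0.894970
4670.70	23.851204	0.842189
4834.37	23.767780	0.792426
5003.78	23.674556	0.745513
5179.12	23.568250	0.701293
5360.61	23.443894	0.659615
5548.46	23.293493	0.620338
5742.89	23.103055	0.583327
5944.14	22.844832	0.548456
6152.43	22.451096	0.515604
6368.03	21.665160	0.484658
6591.18	20.573902	3.900962
6822.15	22.582587	3.648988
7061.22	23.268572	3.452507
7308.66	23.727893	3.271181
7564.77	24.057385	3.097734
7829.86	24.309110	2.931925
8104.23	24.508286	2.773510
8388.23	24.669245	2.622251
8682.17	24.801575	2.477794
8986.41	24.909575	2.340261
9301.32	24.998944	2.209415
9627.26	25.072953	2.085275
9964.62	25.134288	1.967534
10313.81	25.185004	1.855896
10675.23	25.226736	1.750077
11049.31	25.260815	1.649803
11436.51	25.288338	1.554814
11837.27	25.310224	1.464859
12252.08	25.328044	1.379683
12681.42	25.340773	1.299050
13125.80	25.353821	1.222689
13585.76	25.359404	1.149878
14061.84	25.362214	1.081147
14554.60	25.363480	1.016271
15064.63	25.361822	0.955032
15592.53	25.358444	0.897271
16138.93	25.353606	0.842804
16704.48	25.347532	0.791457
17289.84	25.340422	0.743061
17895.72	25.332448	0.697458
18522.83	25.323764	0.654497
19171.91	25.314503	0.614036
19843.74	25.304784	0.575938
20539.12	25.294710	0.540074
21258.86	25.284372	0.506321
22003.82	25.273849	0.474563
22774.88	25.263213	0.444690
23572.97	25.252521	0.416596
24399.02	25.241827	0.390182
25254.02	25.231179	0.365354
26138.98	25.220615	0.342022
27054.96	25.210156	0.320072
28003.03	25.199815	0.299426
28984.32	25.192355	0.279879
30000.00	25.182120	0.261487
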