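# Cl Z=17 f1 f2 vs photon energy (eV); Cromer-Liberman, f1 = Z + f'
E(eV)	f1	f2
250.00	7.821136	12.442731
258.76	8.500327	11.997870
267.83	8.965709	11.559586
277.21	9.613790	12.444006
286.93	10.562217	12.024955
296.98	11.282819	11.612304
307.39	11.890515	11.206398
318.16	12.420502	10.807556
329.31	12.895077	10.416049
340.85	13.397116	10.029615
352.79	13.767555	9.640346
365.16	14.099415	9.261383
377.95	14.397560	8.892709
391.20	14.665729	8.534288
404.91	14.907034	8.186069
419.09	15.124109	7.847986
433.78	15.319226	7.519957
448.98	15.494362	7.201891
464.71	15.687513	6.890492
481.00	15.825513	6.586324
497.85	15.947624	6.292503
515.30	16.055223	6.008875
533.36	16.149550	5.735274
552.05	16.231725	5.471527
571.39	16.302770	5.217448
591.42	16.363615	4.972845
612.14	16.415112	4.737518
633.59	16.458042	4.511263
655.79	16.493120	4.293866
678.78	16.521008	4.085113
702.56	16.542311	3.884784
727.18	16.557587	3.692655
752.66	16.567350	3.508503
779.04	16.572072	3.332099
806.34	16.581463	3.163030
834.59	16.578453	3.000503
863.84	16.568005	2.845510
894.11	16.554278	2.697749
925.44	16.537588	2.556929
957.87	16.518213	2.422766
991.44	16.496398	2.294985
1026.18	16.472788	2.172454
1062.14	16.446780	2.055767
1099.36	16.422859	1.944764
1137.88	16.392359	1.839211
1177.76	16.360075	1.739064
1219.03	16.326153	1.644068
1261.75	16.290687	1.553980
1305.96	16.253731	1.468564
1351.73	16.215294	1.387596
1399.09	16.175348	1.310861
1448.12	16.133823	1.238153
1498.87	16.090604	1.169275
1551.39	16.045524	1.104037
1605.76	15.998358	1.042260
1662.03	15.948809	0.983772
1720.27	15.896494	0.928408
1780.55	15.840917	0.876011
1842.94	15.781441	0.826431
1907.52	15.717236	0.779525
1974.37	15.647211	0.735157
2043.56	15.569901	0.693196
2115.17	15.483299	0.653520
2189.29	15.384566	0.616009
2266.01	15.269528	0.580552
2345.41	15.131732	0.547042
2427.60	14.960488	0.515377
2512.67	14.736286	0.485461
2600.72	14.417776	0.457201
2691.85	13.890636	0.430510
2786.18	12.519646	0.405305
2883.82	13.355786	3.978722
2984.87	14.630710	3.775560
3089.47	15.273554	3.576233
3197.73	15.708419	3.387284
3309.79	16.029891	3.207354
3425.77	16.279904	3.036068
3545.82	16.480097	2.873061
3670.07	16.641312	2.717988
3798.68	16.778240	2.571028
3931.80	16.890518	2.431131
4069.58	16.984437	2.298072
4212.18	17.063164	2.171560
4359.79	17.129155	2.051317
4512.57	17.184363	1.937073
4670.70	17.230369	1.828567
4834.37	17.268473	1.725550
5003.78	17.299758	1.627778
5179.12	17.326243	1.534985
5360.61	17.346374	1.446966
5548.46	17.362053	1.363530
5742.89	17.376889	1.284179
5944.14	17.384889	1.208825
6152.43	17.389931	1.137583
6368.03	17.392418	1.070248
6591.18	17.392698	1.006623
6822.15	17.391079	0.946522
7061.22	17.387828	0.889765
7308.66	17.383181	0.836182
7564.77	17.377348	0.785609
7829.86	17.370511	0.737891
8104.23	17.362865	0.692881
8388.23	17.354477	0.650436
8682.17	17.345519	0.610423
8986.41	17.336108	0.572653
9301.32	17.326307	0.536951
9627.26	17.316198	0.503368
9964.62	17.305875	0.471784
10313.81	17.295416	0.442089
10675.23	17.284889	0.414173
11049.31	17.274351	0.387938
11436.51	17.263851	0.363286
11837.27	17.253431	0.340128
12252.08	17.244893	0.318368
12681.42	17.234549	0.297781
13125.80	17.224392	0.278480
13585.76	17.214435	0.260386
14061.84	17.204697	0.243428
14554.60	17.195193	0.227536
15064.63	17.185937	0.212647
15592.53	17.176938	0.198698
16138.93	17.168202	0.185634
16704.48	17.159735	0.173399
17289.84	17.151540	0.161944
17895.72	17.143618	0.151220
18522.83	17.135969	0.141182
19171.91	17.128592	0.131789
19843.74	17.121483	0.123000
20539.12	17.114641	0.114777
21258.86	17.108061	0.107087
22003.82	17.101738	0.099894
22774.88	17.095667	0.093169
23572.97	17.089843	0.086882
24399.02	17.084259	0.081005
25254.02	17.078909	0.075514
26138.98	17.073788	0.070382
27054.96	17.068881	0.065573
28003.03	17.064179	0.061063
28984.32	17.059684	0.056856
30000.00	17.055389	0.052933
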