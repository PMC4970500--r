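# Se Z=34 f1 f2 vs photon energy (eV); Cromer-Liberman, f1 = Z + f'
E(eV)	f1	f2
250.00	18.168302	15.122640
258.76	18.712661	14.875895
267.83	19.221528	14.626212
277.21	19.940781	14.357917
286.93	20.517528	14.056211
296.98	20.952578	13.737849
307.39	21.363495	13.418194
318.16	21.751976	13.097708
329.31	22.119350	12.776831
340.85	22.466703	12.455984
352.79	22.794945	12.135568
365.16	23.104857	11.815963
377.95	23.397122	11.497529
391.20	23.672570	11.180610
404.91	23.962274	10.860161
419.09	24.203248	10.542321
433.78	24.428102	10.227403
448.98	24.637312	9.915685
464.71	24.831304	9.607428
481.00	25.010458	9.302874
497.85	25.175112	9.002252
515.30	25.325563	8.705770
533.36	25.462064	8.413624
552.05	25.584828	8.125997
571.39	25.694023	7.843054
591.42	25.789768	7.564950
612.14	25.872134	7.291827
633.59	25.941134	7.023815
655.79	26.064842	6.758673
678.78	26.133780	6.494830
702.56	26.151829	6.235733
727.18	26.155671	5.984009
752.66	26.145067	5.739645
779.04	26.119621	5.502612
806.34	26.078747	5.272866
834.59	26.021624	5.050347
863.84	25.947144	4.834982
894.11	25.853830	4.626688
925.44	25.739621	4.425368
957.87	25.602884	4.230864
991.44	25.438208	4.043202
1026.18	25.241498	3.858265
1062.14	25.005801	3.679575
1099.36	24.774349	3.505856
1137.88	24.426839	3.339669
1177.76	24.001048	3.180885
1219.03	23.465426	3.029176
1261.75	22.762977	2.884232
1305.96	21.772985	2.745757
1351.73	20.157602	2.613467
1399.09	16.232518	2.487094
1448.12	15.021507	29.356865
1498.87	30.309329	22.690381
1551.39	22.350903	14.603040
1605.76	24.087912	13.836878
1662.03	24.571604	15.013013
1720.27	27.030205	14.257295
1780.55	28.316749	13.555146
1842.94	29.304488	12.889148
1907.52	30.078009	12.256389
1974.37	30.724667	11.655216
2043.56	31.275533	11.079472
2115.17	31.742105	10.527813
2189.29	32.142161	9.999005
2266.01	32.481123	9.492542
2345.41	32.770774	9.008182
2427.60	33.018142	8.545194
2512.67	33.228950	8.102853
2600.72	33.407934	7.680446
2691.85	33.559074	7.277271
2786.18	33.685754	6.892640
2883.82	33.791688	6.525855
2984.87	33.877081	6.176286
3089.47	33.958577	5.841229
3197.73	34.015455	5.522473
3309.79	34.058139	5.219864
3425.77	34.083839	4.931999
3545.82	34.099283	4.659076
3670.07	34.105766	4.400385
3798.68	34.104430	4.155242
3931.80	34.096259	3.922993
4069.58	34.082112	3.703013
4212.18	34.062739	3.494702
4359.79	34.038702	3.297487
4512.57	34.010775	3.110822
4670.70	33.979356	2.934178
4834.37	33.944879	2.767054
5003.78	33.907719	2.608972
5179.12	33.868196	2.459473
5360.61	33.826580	2.318121
5548.46	33.783091	2.184501
5742.89	33.737904	2.058214
5944.14	33.691149	1.938883
6152.43	33.642912	1.826147
6368.03	33.595117	1.719530
6591.18	33.544726	1.618735
6822.15	33.491639	1.523630
7061.22	33.436984	1.433918
7308.66	33.381632	1.349243
7564.77	33.323045	1.269374
7829.86	33.262149	1.194098
8104.23	33.198495	1.123159
8388.23	33.131487	1.056313
8682.17	33.060334	0.993332
8986.41	32.984221	0.933710
9301.32	32.901818	0.876913
9627.26	32.810433	0.823536
9964.62	32.707265	0.773373
10313.81	32.588022	0.726231
10675.23	32.445815	0.681931
11049.31	32.268747	0.640301
11436.51	32.033784	0.601180
11837.27	31.687186	0.564420
12252.08	31.046723	0.529878
12681.42	28.226487	3.828724
13125.80	31.554449	3.562709
13585.76	32.273674	3.356799
14061.84	32.736525	3.177675
14554.60	33.061616	3.006966
15064.63	33.306750	2.844342
15592.53	33.498910	2.689481
16138.93	33.653100	2.542072
16704.48	33.781946	2.401318
17289.84	33.884537	2.266999
17895.72	33.969019	2.139528
18522.83	34.038728	2.018594
19171.91	34.096205	1.903900
19843.74	34.143438	1.795159
20539.12	34.182017	1.692095
21258.86	34.213235	1.594446
22003.82	34.238158	1.501955
22774.88	34.257680	1.414381
23572.97	34.272550	1.331489
24399.02	34.283410	1.253055
25254.02	34.290818	1.178864
26138.98	34.295329	1.108690
27054.96	34.297454	1.042219
28003.03	34.297370	0.979210
28984.32	34.294957	0.919822
30000.00	34.290776	0.863859
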