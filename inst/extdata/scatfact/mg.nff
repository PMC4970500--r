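# Mg Z=12 f1 f2 vs photon energy (eV); Cromer-Liberman, f1 = Z + f'
E(eV)	f1	f2
250.00	10.780455	3.816785
258.76	10.824960	3.652023
267.83	10.863658	3.493101
277.21	10.896992	3.339884
286.93	10.925369	3.192236
296.98	10.949165	3.050017
307.39	10.968723	2.913090
318.16	10.984358	2.781316
329.31	10.996362	2.654554
340.85	11.005001	2.532667
352.79	11.010519	2.415515
365.16	11.039215	2.301461
377.95	11.037698	2.191124
391.20	11.033562	2.085385
404.91	11.027000	1.984098
419.09	11.018184	1.887120
433.78	11.007268	1.794308
448.98	10.994384	1.705523
464.71	10.979648	1.620625
481.00	10.963157	1.539478
497.85	10.944989	1.461950
515.30	10.925204	1.387907
533.36	10.903845	1.317223
552.05	10.880931	1.249770
571.39	10.856464	1.185425
591.42	10.830422	1.124070
612.14	10.802757	1.065585
633.59	10.773396	1.009858
655.79	10.742232	0.956777
678.78	10.709123	0.906234
702.56	10.673884	0.858124
727.18	10.636278	0.812346
752.66	10.596006	0.768801
779.04	10.552690	0.727394
806.34	10.505850	0.688031
834.59	10.454880	0.650625
863.84	10.399001	0.615088
894.11	10.337200	0.581339
925.44	10.268141	0.549295
957.87	10.190023	0.518881
991.44	10.100424	0.490017
1026.18	9.997340	0.462315
1062.14	9.872271	0.436025
1099.36	9.717584	0.411195
1137.88	9.519178	0.387742
1177.76	9.249346	0.365591
1219.03	8.844367	0.344671
1261.75	8.096893	0.324912
1305.96	3.718502	3.956072
1351.73	8.337000	4.046252
1399.09	9.612503	3.922030
1448.12	10.212053	3.710625
1498.87	10.633704	3.510420
1551.39	10.952638	3.320833
1605.76	11.203775	3.141310
1662.03	11.406496	2.971324
1720.27	11.557513	2.812726
1780.55	11.698070	2.665154
1842.94	11.816653	2.524304
1907.52	11.917097	2.389931
1974.37	12.002344	2.261795
2043.56	12.074715	2.139660
2115.17	12.136075	2.023297
2189.29	12.187951	1.912485
2266.01	12.231610	1.807005
2345.41	12.268120	1.706646
2427.60	12.298385	1.611202
2512.67	12.323182	1.520474
2600.72	12.343198	1.434268
2691.85	12.360008	1.352217
2786.18	12.371700	1.274430
2883.82	12.380172	1.200736
2984.87	12.385834	1.130944
3089.47	12.389526	1.064299
3197.73	12.390807	1.001232
3309.79	12.390015	0.941666
3425.77	12.387490	0.885422
3545.82	12.383507	0.832326
3670.07	12.378296	0.782218
3798.68	12.372053	0.734941
3931.80	12.364947	0.690346
4069.58	12.357127	0.648294
4212.18	12.348720	0.608648
4359.79	12.339841	0.571283
4512.57	12.330590	0.536075
4670.70	12.321054	0.502909
4834.37	12.311310	0.471674
5003.78	12.301426	0.442267
5179.12	12.291461	0.414588
5360.61	12.281468	0.388542
5548.46	12.271492	0.364039
5742.89	12.262806	0.340936
5944.14	12.252811	0.319165
6152.43	12.242941	0.298726
6368.03	12.233227	0.279540
6591.18	12.223690	0.261535
6822.15	12.214350	0.244641
7061.22	12.205222	0.228794
7308.66	12.196319	0.213931
7564.77	12.187649	0.199993
7829.86	12.179222	0.186927
8104.23	12.171042	0.174680
8388.23	12.163114	0.163203
8682.17	12.155438	0.152450
8986.41	12.148026	0.142343
9301.32	12.140874	0.132805
9627.26	12.133956	0.123888
9964.62	12.127276	0.115552
10313.81	12.120835	0.107762
10675.23	12.114632	0.100482
11049.31	12.108665	0.093681
11436.51	12.102931	0.087327
11837.27	12.097427	0.081392
12252.08	12.092147	0.075849
12681.42	12.087086	0.070673
13125.80	12.082240	0.065841
13585.76	12.077602	0.061330
14061.84	12.073167	0.057120
14554.60	12.068927	0.053191
15064.63	12.064878	0.049525
15592.53	12.061012	0.046105
16138.93	12.057324	0.042915
16704.48	12.053806	0.039939
17289.84	12.050453	0.037165
17895.72	12.047259	0.034577
18522.83	12.044217	0.032166
19171.91	12.041322	0.029918
19843.74	12.038567	0.027823
20539.12	12.035947	0.025871
21258.86	12.033456	0.024052
22003.82	12.031089	0.022358
22774.88	12.028841	0.020780
23572.97	12.026705	0.019310
24399.02	12.024679	0.017942
25254.02	12.022755	0.016669
26138.98	12.020931	0.015483
27054.96	12.019199	0.014379
28003.03	12.017554	0.013353
28984.32	12.015996	0.012398
30000.00	12.014521	0.011510
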