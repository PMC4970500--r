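# Na Z=11 f1 f2 vs photon energy (eV); Cromer-Liberman, f1 = Z + f'
E(eV)	f1	f2
250.00	9.766819	2.646090
258.76	9.832033	2.531235
267.83	9.845420	2.418811
277.21	9.855622	2.310443
286.93	9.862848	2.206044
296.98	9.867293	2.105527
307.39	9.869135	2.008804
318.16	9.868538	1.915783
329.31	9.865649	1.826372
340.85	9.860601	1.740476
352.79	9.853514	1.658002
365.16	9.844493	1.578854
377.95	9.833627	1.502938
391.20	9.820993	1.430158
404.91	9.806650	1.360418
419.09	9.790644	1.293626
433.78	9.773004	1.229686
448.98	9.753741	1.168505
464.71	9.732848	1.109992
481.00	9.710296	1.054056
497.85	9.686035	1.000606
515.30	9.659988	0.949554
533.36	9.632049	0.900815
552.05	9.602078	0.854302
571.39	9.569893	0.809932
591.42	9.549456	0.767353
612.14	9.510291	0.726420
633.59	9.468178	0.687560
655.79	9.422650	0.650673
678.78	9.373120	0.615662
702.56	9.318835	0.582433
727.18	9.258827	0.550901
752.66	9.191824	0.520980
779.04	9.116124	0.492591
806.34	9.029390	0.465659
834.59	8.928312	0.440112
863.84	8.808012	0.415882
894.11	8.660913	0.392902
925.44	8.474412	0.371112
957.87	8.225398	0.350452
991.44	7.864733	0.330866
1026.18	7.256430	0.312128
1062.14	5.605068	0.294364
1099.36	6.283633	3.757037
1137.88	8.291877	4.084691
1177.76	8.995056	3.858067
1219.03	9.475448	3.644369
1261.75	9.828755	3.442931
1305.96	10.103316	3.253072
1351.73	10.322838	3.074102
1399.09	10.473671	2.906458
1448.12	10.625045	2.755662
1498.87	10.752902	2.611647
1551.39	10.861397	2.474167
1605.76	10.953704	2.342984
1662.03	11.032312	2.217865
1720.27	11.099216	2.098584
1780.55	11.156046	1.984919
1842.94	11.204148	1.876653
1907.52	11.244655	1.773576
1974.37	11.278526	1.675483
2043.56	11.306582	1.582175
2115.17	11.329532	1.493458
2189.29	11.351172	1.408780
2266.01	11.365141	1.328239
2345.41	11.375629	1.251910
2427.60	11.383077	1.179598
2512.67	11.387868	1.111114
2600.72	11.390343	1.046278
2691.85	11.390799	0.984915
2786.18	11.389503	0.926859
2883.82	11.386688	0.871951
2984.87	11.382563	0.820037
3089.47	11.377289	0.770655
3197.73	11.370986	0.724014
3309.79	11.363827	0.680031
3425.77	11.355963	0.638564
3545.82	11.347525	0.599480
3670.07	11.338628	0.562650
3798.68	11.329371	0.527953
3931.80	11.319841	0.495275
4069.58	11.310114	0.464506
4212.18	11.300259	0.435542
4359.79	11.290332	0.408284
4512.57	11.280386	0.382637
4670.70	11.272107	0.358487
4834.37	11.262074	0.335652
5003.78	11.252138	0.314211
5179.12	11.242334	0.294082
5360.61	11.232689	0.275189
5548.46	11.223225	0.257459
5742.89	11.213959	0.240824
5944.14	11.204906	0.225220
6152.43	11.196079	0.210586
6368.03	11.187487	0.196865
6591.18	11.179136	0.184001
6822.15	11.171033	0.171944
7061.22	11.163180	0.160645
7308.66	11.155579	0.150060
7564.77	11.148231	0.140144
7829.86	11.141136	0.130858
8104.23	11.134291	0.122164
8388.23	11.127695	0.114024
8682.17	11.121343	0.106406
8986.41	11.115228	0.099256
9301.32	11.109333	0.092521
9627.26	11.103666	0.086231
9964.62	11.098224	0.080357
10313.81	11.093003	0.074872
10675.23	11.087998	0.069752
11049.31	11.083204	0.064973
11436.51	11.078616	0.060512
11837.27	11.074227	0.056349
12252.08	11.070032	0.052466
12681.42	11.066025	0.048843
13125.80	11.062199	0.045463
13585.76	11.058548	0.042312
14061.84	11.055067	0.039373
14554.60	11.051749	0.036633
15064.63	11.048588	0.034078
15592.53	11.045577	0.031698
16138.93	11.042711	0.029479
16704.48	11.039984	0.027412
17289.84	11.037391	0.025486
17895.72	11.034926	0.023692
18522.83	11.032584	0.022021
19171.91	11.030359	0.020464
19843.74	11.028246	0.019016
20539.12	11.026241	0.017667
21258.86	11.024338	0.016411
22003.82	11.022533	0.015243
22774.88	11.020820	0.014155
23572.97	11.019220	0.013143
24399.02	11.017676	0.012201
25254.02	11.016214	0.011326
26138.98	11.014830	0.010512
27054.96	11.013521	0.009756
28003.03	11.012283	0.009053
28984.32	11.011112	0.008400
30000.00	11.010005	0.007793
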