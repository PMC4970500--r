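# Zn Z=30 f1 f2 vs photon energy (eV); Cromer-Liberman, f1 = Z + f'
E(eV)	f1	f2
250.00	18.164094	8.738637
258.76	18.344718	8.556650
267.83	18.519260	8.376471
277.21	18.687853	8.197962
286.93	18.850584	8.020979
296.98	19.007492	7.845376
307.39	19.158574	7.671008
318.16	19.303781	7.497733
329.31	19.443018	7.325413
340.85	19.576149	7.153920
352.79	20.131467	6.961579
365.16	20.237988	6.752956
377.95	20.334784	6.547785
391.20	20.421910	6.346124
404.91	20.499371	6.148026
419.09	20.567124	5.953532
433.78	20.625070	5.762679
448.98	20.673047	5.575498
464.71	20.710828	5.392013
481.00	20.738107	5.212243
497.85	20.754488	5.036201
515.30	20.759468	4.863898
533.36	20.752417	4.695337
552.05	20.746484	4.529928
571.39	20.711870	4.367670
591.42	20.662224	4.209331
612.14	20.596068	4.054895
633.59	20.511548	3.904341
655.79	20.406316	3.757648
678.78	20.277368	3.614787
702.56	20.120805	3.475731
727.18	19.931476	3.340448
752.66	19.702421	3.208902
779.04	19.423961	3.081058
806.34	19.082130	2.956877
834.59	18.655750	2.836317
863.84	18.110405	2.719337
894.11	17.384206	2.605891
925.44	16.346629	2.495933
957.87	14.636071	2.389415
991.44	10.522156	2.286287
1026.18	4.237630	35.752125
1062.14	27.553154	24.664931
1099.36	17.461481	15.725777
1137.88	19.570070	14.818234
1177.76	20.519511	13.967009
1219.03	22.077815	14.977333
1261.75	23.624534	14.196334
1305.96	24.707065	13.471332
1351.73	25.448543	12.807987
1399.09	26.108758	12.205774
1448.12	26.710581	11.628124
1498.87	27.224381	11.072887
1551.39	27.665880	10.539444
1605.76	28.058471	10.023191
1662.03	28.402650	9.527782
1720.27	28.683345	9.052979
1780.55	28.925148	8.598484
1842.94	29.133007	8.163643
1907.52	29.311076	7.747813
1974.37	29.462885	7.350357
2043.56	29.601272	6.970536
2115.17	29.712901	6.605972
2189.29	29.800330	6.258067
2266.01	29.871466	5.926762
2345.41	29.928176	5.611371
2427.60	29.974093	5.311046
2512.67	30.006281	5.025239
2600.72	30.028594	4.753543
2691.85	30.041718	4.495350
2786.18	30.046937	4.250076
2883.82	30.045156	4.017148
2984.87	30.037182	3.796016
3089.47	30.023954	3.584744
3197.73	30.005556	3.384349
3309.79	29.982615	3.194562
3425.77	29.955728	3.014862
3545.82	29.925405	2.844751
3670.07	29.892081	2.683754
3798.68	29.856979	2.531398
3931.80	29.818593	2.387269
4069.58	29.778164	2.250952
4212.18	29.735901	2.122050
4359.79	29.691968	2.000185
4512.57	29.650379	1.884750
4670.70	29.605071	1.775356
4834.37	29.556014	1.672089
5003.78	29.505546	1.574627
5179.12	29.456591	1.482643
5360.61	29.402759	1.395587
5548.46	29.347214	1.313497
5742.89	29.289669	1.236098
5944.14	29.229791	1.163130
6152.43	29.167132	1.094348
6368.03	29.101100	1.029520
6591.18	29.030914	0.968423
6822.15	28.955530	0.910851
7061.22	28.873529	0.856605
7308.66	28.782948	0.805498
7564.77	28.680972	0.757354
7829.86	28.563410	0.712007
8104.23	28.423661	0.669297
8388.23	28.250523	0.629075
8682.17	28.022802	0.591200
8986.41	27.692810	0.555386
9301.32	27.111289	0.521333
9627.26	24.657850	0.489343
9964.62	27.305756	3.659024
10313.81	28.142573	3.444263
10675.23	28.648144	3.261965
11049.31	28.998467	3.088082
11436.51	29.261008	2.922297
11837.27	29.466189	2.764298
12252.08	29.630353	2.613786
12681.42	29.771613	2.470002
13125.80	29.879736	2.332253
13585.76	29.969848	2.201520
14061.84	30.044405	2.077485
14554.60	30.106050	1.959841
15064.63	30.156882	1.848295
15592.53	30.198582	1.742564
16138.93	30.232515	1.642377
16704.48	30.259805	1.547474
17289.84	30.281384	1.457604
17895.72	30.298027	1.372529
18522.83	30.310328	1.292018
19171.91	30.317366	1.215852
19843.74	30.327533	1.143566
20539.12	30.329815	1.075238
21258.86	30.329998	1.010743
22003.82	30.328298	0.949879
22774.88	30.324859	0.892455
23572.97	30.319917	0.838295
24399.02	30.313753	0.787227
25254.02	30.306562	0.739086
26138.98	30.298540	0.693716
27054.96	30.289761	0.650897
28003.03	30.280382	0.610481
28984.32	30.270523	0.572460
30000.00	30.260299	0.536699
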