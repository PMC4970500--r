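# Ca Z=20 f1 f2 vs photon energy (eV); Cromer-Liberman, f1 = Z + f'
E(eV)	f1	f2
250.00	8.177432	1.790078
258.76	7.952832	1.752082
267.83	7.677854	1.713496
277.21	7.338270	1.674396
286.93	6.913368	1.634861
296.98	6.371629	1.594967
307.39	5.662352	1.554789
318.16	4.697940	1.514404
329.31	3.311809	1.473883
340.85	1.140817	1.433298
352.79	-2.220572	15.562581
365.16	4.101289	14.962466
377.95	6.901856	14.374661
391.20	8.727310	13.799555
404.91	10.042322	13.237491
419.09	11.005155	12.688772
433.78	11.650764	12.153658
448.98	12.460248	13.181577
464.71	13.608046	12.663445
481.00	14.515414	12.157426
497.85	15.213161	11.662486
515.30	15.807998	11.181070
533.36	16.323636	10.713208
552.05	16.774836	10.258900
571.39	17.171883	9.818120
591.42	17.553891	9.389235
612.14	17.875070	8.968159
633.59	18.143838	8.562095
655.79	18.380805	8.170734
678.78	18.589548	7.793751
702.56	18.773109	7.430815
727.18	18.934111	7.081591
752.66	19.083123	6.745025
779.04	19.204395	6.421071
806.34	19.309075	6.110188
834.59	19.399212	5.812001
863.84	19.475345	5.526152
894.11	19.539282	5.252286
925.44	19.592195	4.990040
957.87	19.635141	4.739049
991.44	19.669074	4.498955
1026.18	19.694078	4.267381
1062.14	19.711175	4.045943
1099.36	19.721413	3.834972
1137.88	19.725540	3.634042
1177.76	19.724216	3.442742
1219.03	19.718031	3.260671
1261.75	19.707508	3.087442
1305.96	19.693111	2.922678
1351.73	19.675248	2.766017
1399.09	19.661519	2.616916
1448.12	19.640663	2.474488
1498.87	19.613290	2.339346
1551.39	19.583707	2.211152
1605.76	19.552127	2.089577
1662.03	19.518724	1.974303
1720.27	19.483637	1.865028
1780.55	19.450702	1.761291
1842.94	19.412162	1.662854
1907.52	19.372148	1.569649
1974.37	19.330664	1.481416
2043.56	19.287677	1.397907
2115.17	19.243110	1.318884
2189.29	19.196837	1.244122
2266.01	19.148678	1.173404
2345.41	19.098391	1.106524
2427.60	19.045652	1.043286
2512.67	18.990040	0.983502
2600.72	18.931011	0.926994
2691.85	18.867855	0.873591
2786.18	18.799637	0.823133
2883.82	18.725116	0.775463
2984.87	18.642598	0.730437
3089.47	18.549685	0.687537
3197.73	18.442949	0.647021
3309.79	18.317232	0.608824
3425.77	18.164226	0.572817
3545.82	17.969396	0.538878
3670.07	17.703936	0.506891
3798.68	17.297666	0.476746
3931.80	16.485959	0.448342
4069.58	15.312372	3.998803
4212.18	17.421008	3.755512
4359.79	18.157657	3.554293
4512.57	18.639241	3.367186
4670.70	18.984605	3.188779
4834.37	19.248538	3.018732
5003.78	19.457583	2.856718
5179.12	19.626834	2.702418
5360.61	19.766574	2.555360
5548.46	19.881579	2.415359
5742.89	19.977325	2.282233
5944.14	20.057249	2.155692
6152.43	20.123986	2.035454
6368.03	20.179611	1.921249
6591.18	20.226213	1.812809
6822.15	20.264234	1.709876
7061.22	20.295312	1.612224
7308.66	20.320394	1.519616
7564.77	20.340282	1.431826
7829.86	20.355661	1.348632
8104.23	20.367721	1.269812
8388.23	20.375635	1.195120
8682.17	20.380437	1.124500
8986.41	20.383105	1.057570
9301.32	20.383957	0.993936
9627.26	20.382370	0.933922
9964.62	20.378902	0.877336
10313.81	20.373916	0.823992
10675.23	20.367683	0.773718
11049.31	20.360426	0.726347
11436.51	20.352328	0.681722
11837.27	20.343590	0.639693
12252.08	20.334255	0.600118
12681.42	20.324490	0.562863
13125.80	20.314397	0.527800
13585.76	20.304065	0.494809
14061.84	20.293571	0.463773
14554.60	20.282983	0.434584
15064.63	20.272360	0.407138
15592.53	20.261751	0.381337
16138.93	20.251202	0.357089
16704.48	20.240749	0.334306
17289.84	20.230429	0.312904
17895.72	20.221283	0.292734
18522.83	20.211152	0.273780
19171.91	20.201229	0.256010
19843.74	20.191534	0.239353
20539.12	20.182068	0.223741
21258.86	20.172866	0.209112
22003.82	20.163925	0.195405
22774.88	20.155249	0.182566
23572.97	20.146844	0.170540
24399.02	20.138711	0.159280
25254.02	20.130852	0.148737
26138.98	20.123265	0.138868
27054.96	20.115976	0.129564
28003.03	20.108971	0.120770
28984.32	20.102200	0.112563
30000.00	20.095668	0.104904
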