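# C Z=6 f1 f2 vs photon energy (eV); Cromer-Liberman, f1 = Z + f'
E(eV)	f1	f2
250.00	3.135912	0.212096
258.76	2.886150	0.202679
267.83	2.533045	0.193618
277.21	1.990026	0.184901
286.93	0.706386	3.961549
296.98	2.594179	3.804562
307.39	3.391351	3.651317
318.16	3.912538	3.501865
329.31	4.299968	3.356249
340.85	4.606402	3.214501
352.79	4.857617	3.076645
365.16	5.068303	2.942696
377.95	5.251962	2.812462
391.20	5.405995	2.686155
404.91	5.539468	2.563786
419.09	5.655699	2.445336
433.78	5.757236	2.330781
448.98	5.846096	2.220088
464.71	5.923908	2.113219
481.00	6.032538	2.009544
497.85	6.088462	1.903876
515.30	6.136298	1.803136
533.36	6.177094	1.707131
552.05	6.211716	1.615675
571.39	6.240909	1.528584
591.42	6.265315	1.445684
612.14	6.285494	1.366803
633.59	6.301936	1.291775
655.79	6.315072	1.220439
678.78	6.325284	1.152641
702.56	6.332911	1.088228
727.18	6.338252	1.027057
752.66	6.341578	0.968986
779.04	6.343127	0.913879
806.34	6.343115	0.861604
834.59	6.341735	0.812037
863.84	6.339158	0.765053
894.11	6.335542	0.720536
925.44	6.331026	0.678372
957.87	6.325735	0.638453
991.44	6.319782	0.600672
1026.18	6.313124	0.564861
1062.14	6.305958	0.531013
1099.36	6.298421	0.499056
1137.88	6.294140	0.468869
1177.76	6.285775	0.440103
1219.03	6.277234	0.413009
1261.75	6.268588	0.387496
1305.96	6.259888	0.363477
1351.73	6.251178	0.340872
1399.09	6.242495	0.319600
1448.12	6.233872	0.299588
1498.87	6.225337	0.280767
1551.39	6.216916	0.263069
1605.76	6.208627	0.246432
1662.03	6.200490	0.230794
1720.27	6.192518	0.216101
1780.55	6.184724	0.202298
1842.94	6.177118	0.189333
1907.52	6.169708	0.177160
1974.37	6.162500	0.165733
2043.56	6.155498	0.155007
2115.17	6.148706	0.144943
2189.29	6.142126	0.135502
2266.01	6.135758	0.126648
2345.41	6.129602	0.118346
2427.60	6.123658	0.110563
2512.67	6.117924	0.103268
2600.72	6.112397	0.096433
2691.85	6.107075	0.090031
2786.18	6.101953	0.084034
2883.82	6.097030	0.078419
2984.87	6.092300	0.073163
3089.47	6.087745	0.068226
3197.73	6.083372	0.063607
3309.79	6.079179	0.059289
3425.77	6.075162	0.055254
3545.82	6.071316	0.051484
3670.07	6.067636	0.047963
3798.68	6.064118	0.044673
3931.80	6.060755	0.041602
4069.58	6.057544	0.038734
4212.18	6.054478	0.036057
4359.79	6.051553	0.033559
4512.57	6.048763	0.031228
4670.70	6.046104	0.029054
4834.37	6.043571	0.027026
5003.78	6.041158	0.025134
5179.12	6.038861	0.023371
5360.61	6.036839	0.021726
5548.46	6.034739	0.020187
5742.89	6.032743	0.018754
5944.14	6.030848	0.017421
6152.43	6.029048	0.016180
6368.03	6.027339	0.015026
6591.18	6.025718	0.013952
6822.15	6.024180	0.012953
7061.22	6.022722	0.012024
7308.66	6.021339	0.011160
7564.77	6.020029	0.010357
7829.86	6.018789	0.009610
8104.23	6.017614	0.008916
8388.23	6.016501	0.008271
8682.17	6.015448	0.007672
8986.41	6.014461	0.007113
9301.32	6.013525	0.006589
9627.26	6.012636	0.006103
9964.62	6.011795	0.005653
10313.81	6.010999	0.005236
10675.23	6.010245	0.004849
11049.31	6.009533	0.004491
11436.51	6.008861	0.004158
11837.27	6.008225	0.003850
12252.08	6.007625	0.003565
12681.42	6.007059	0.003301
13125.80	6.006524	0.003056
13585.76	6.006020	0.002829
14061.84	6.005544	0.002618
14554.60	6.005096	0.002423
15064.63	6.004673	0.002243
15592.53	6.004275	0.002076
16138.93	6.003900	0.001921
16704.48	6.003546	0.001777
17289.84	6.003213	0.001645
17895.72	6.002900	0.001522
18522.83	6.002605	0.001408
19171.91	6.002327	0.001302
19843.74	6.002065	0.001205
20539.12	6.001819	0.001114
21258.86	6.001588	0.001031
22003.82	6.001370	0.000953
22774.88	6.001165	0.000881
23572.97	6.000972	0.000815
24399.02	6.000791	0.000754
25254.02	6.000621	0.000697
26138.98	6.000461	0.000644
27054.96	6.000310	0.000595
28003.03	6.000168	0.000550
28984.32	6.000035	0.000507
30000.00	5.999910	0.000468
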