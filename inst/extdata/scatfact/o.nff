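# O Z=8 f1 f2 vs photon energy (eV); Cromer-Liberman, f1 = Z + f'
E(eV)	f1	f2
250.00	6.369305	0.647928
258.76	6.349657	0.618780
267.83	6.328276	0.590850
277.21	6.304971	0.564085
286.93	6.279512	0.538437
296.98	6.251619	0.513860
307.39	6.220954	0.490309
318.16	6.187105	0.467742
329.31	6.149561	0.446119
340.85	6.107690	0.425401
352.79	6.060692	0.405551
365.16	6.007549	0.386534
377.95	5.946933	0.368318
391.20	5.877090	0.350869
404.91	5.795634	0.334158
419.09	5.699243	0.318155
433.78	5.583121	0.302832
448.98	5.450136	0.288029
464.71	5.268003	0.273517
481.00	5.028454	0.259690
497.85	4.696377	0.246516
515.30	4.199321	0.233966
533.36	0.829596	4.157470
552.05	4.376247	3.983370
571.39	5.323129	3.813541
591.42	5.907467	3.648060
612.14	6.330662	3.486991
633.59	6.659969	3.330387
655.79	6.926625	3.178285
678.78	7.147910	3.030716
702.56	7.334495	2.887696
727.18	7.493498	2.749230
752.66	7.629948	2.615314
779.04	7.747556	2.485934
806.34	7.849160	2.361066
834.59	7.936996	2.240677
863.84	8.012861	2.124724
894.11	8.078214	2.013158
925.44	8.140088	1.905097
957.87	8.185270	1.802003
991.44	8.223450	1.703905
1026.18	8.256107	1.610115
1062.14	8.283131	1.520862
1099.36	8.305154	1.436116
1137.88	8.322870	1.355675
1177.76	8.336840	1.279347
1219.03	8.347538	1.206945
1261.75	8.355372	1.138291
1305.96	8.360698	1.073211
1351.73	8.363829	1.011541
1399.09	8.365039	0.953121
1448.12	8.364576	0.897799
1498.87	8.362655	0.845428
1551.39	8.359470	0.795866
1605.76	8.355195	0.748978
1662.03	8.349983	0.704636
1720.27	8.343972	0.662715
1780.55	8.337285	0.623095
1842.94	8.330032	0.585663
1907.52	8.322311	0.550311
1974.37	8.314209	0.516932
2043.56	8.305805	0.485428
2115.17	8.297162	0.455704
2189.29	8.289985	0.427541
2266.01	8.280796	0.400997
2345.41	8.271560	0.376016
2427.60	8.262322	0.352509
2512.67	8.253120	0.330395
2600.72	8.243988	0.309597
2691.85	8.234955	0.290042
2786.18	8.226047	0.271659
2883.82	8.217285	0.254382
2984.87	8.208686	0.238149
3089.47	8.200324	0.222797
3197.73	8.192129	0.208378
3309.79	8.184142	0.194853
3425.77	8.176311	0.182169
3545.82	8.168683	0.170279
3670.07	8.161269	0.159133
3798.68	8.154074	0.148687
3931.80	8.147103	0.138900
4069.58	8.140357	0.129732
4212.18	8.133838	0.121145
4359.79	8.127544	0.113104
4512.57	8.121476	0.105576
4670.70	8.115630	0.098530
4834.37	8.110004	0.091936
5003.78	8.104593	0.085767
5179.12	8.099395	0.079995
5360.61	8.094405	0.074598
5548.46	8.089617	0.069551
5742.89	8.085027	0.064832
5944.14	8.080630	0.060422
6152.43	8.076420	0.056300
6368.03	8.072392	0.052450
6591.18	8.068539	0.048853
6822.15	8.064858	0.045494
7061.22	8.061341	0.042357
7308.66	8.057983	0.039429
7564.77	8.054779	0.036696
7829.86	8.051722	0.034146
8104.23	8.048809	0.031767
8388.23	8.046032	0.029547
8682.17	8.043388	0.027478
8986.41	8.040866	0.025547
9301.32	8.038456	0.023747
9627.26	8.036165	0.022070
9964.62	8.033986	0.020509
10313.81	8.032171	0.019043
10675.23	8.030180	0.017680
11049.31	8.028303	0.016412
11436.51	8.026509	0.015234
11837.27	8.024808	0.014139
12252.08	8.023196	0.013122
12681.42	8.021668	0.012176
13125.80	8.020221	0.011298
13585.76	8.018850	0.010482
14061.84	8.017553	0.009724
14554.60	8.016325	0.009020
15064.63	8.015163	0.008366
15592.53	8.014064	0.007759
16138.93	8.013025	0.007195
16704.48	8.012043	0.006672
17289.84	8.011115	0.006186
17895.72	8.010238	0.005735
18522.83	8.009410	0.005316
19171.91	8.008628	0.004927
19843.74	8.007889	0.004567
20539.12	8.007192	0.004232
21258.86	8.006535	0.003922
22003.82	8.005914	0.003634
22774.88	8.005329	0.003367
23572.97	8.004777	0.003119
24399.02	8.004256	0.002889
25254.02	8.003766	0.002676
26138.98	8.003303	0.002478
27054.96	8.002868	0.002294
28003.03	8.002458	0.002122
28984.32	8.002071	0.001962
30000.00	8.001707	0.001815
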