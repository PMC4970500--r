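# H Z=1 f1 f2 vs photon energy (eV); Cromer-Liberman, f1 = Z + f'
E(eV)	f1	f2
250.00	1.000000	0.000000
258.76	1.000000	0.000000
267.83	1.000000	0.000000
277.21	1.000000	0.000000
286.93	1.000000	0.000000
296.98	1.000000	0.000000
307.39	1.000000	0.000000
318.16	1.000000	0.000000
329.31	1.000000	0.000000
340.85	1.000000	0.000000
352.79	1.000000	0.000000
365.16	1.000000	0.000000
377.95	1.000000	0.000000
391.20	1.000000	0.000000
404.91	1.000000	0.000000
419.09	1.000000	0.000000
433.78	1.000000	0.000000
448.98	1.000000	0.000000
464.71	1.000000	0.000000
481.00	1.000000	0.000000
497.85	1.000000	0.000000
515.30	1.000000	0.000000
533.36	1.000000	0.000000
552.05	1.000000	0.000000
571.39	1.000000	0.000000
591.42	1.000000	0.000000
612.14	1.000000	0.000000
633.59	1.000000	0.000000
655.79	1.000000	0.000000
678.78	1.000000	0.000000
702.56	1.000000	0.000000
727.18	1.000000	0.000000
752.66	1.000000	0.000000
779.04	1.000000	0.000000
806.34	1.000000	0.000000
834.59	1.000000	0.000000
863.84	1.000000	0.000000
894.11	1.000000	0.000000
925.44	1.000000	0.000000
957.87	1.000000	0.000000
991.44	1.000000	0.000000
1026.18	1.000000	0.000000
1062.14	1.000000	0.000000
1099.36	1.000000	0.000000
1137.88	1.000000	0.000000
1177.76	1.000000	0.000000
1219.03	1.000000	0.000000
1261.75	1.000000	0.000000
1305.96	1.000000	0.000000
1351.73	1.000000	0.000000
1399.09	1.000000	0.000000
1448.12	1.000000	0.000000
1498.87	1.000000	0.000000
1551.39	1.000000	0.000000
1605.76	1.000000	0.000000
1662.03	1.000000	0.000000
1720.27	1.000000	0.000000
1780.55	1.000000	0.000000
1842.94	1.000000	0.000000
1907.52	1.000000	0.000000
1974.37	1.000000	0.000000
2043.56	1.000000	0.000000
2115.17	1.000000	0.000000
2189.29	1.000000	0.000000
2266.01	1.000000	0.000000
2345.41	1.000000	0.000000
2427.60	1.000000	0.000000
2512.67	1.000000	0.000000
2600.72	1.000000	0.000000
2691.85	1.000000	0.000000
2786.18	1.000000	0.000000
2883.82	1.000000	0.000000
2984.87	1.000000	0.000000
3089.47	1.000000	0.000000
3197.73	1.000000	0.000000
3309.79	1.000000	0.000000
3425.77	1.000000	0.000000
3545.82	1.000000	0.000000
3670.07	1.000000	0.000000
3798.68	1.000000	0.000000
3931.80	1.000000	0.000000
4069.58	1.000000	0.000000
4212.18	1.000000	0.000000
4359.79	1.000000	0.000000
4512.57	1.000000	0.000000
4670.70	1.000000	0.000000
4834.37	1.000000	0.000000
5003.78	1.000000	0.000000
5179.12	1.000000	0.000000
5360.61	1.000000	0.000000
5548.46	1.000000	0.000000
5742.89	1.000000	0.000000
5944.14	1.000000	0.000000
6152.43	1.000000	0.000000
6368.03	1.000000	0.000000
6591.18	1.000000	0.000000
6822.15	1.000000	0.000000
7061.22	1.000000	0.000000
7308.66	1.000000	0.000000
7564.77	1.000000	0.000000
7829.86	1.000000	0.000000
8104.23	1.000000	0.000000
8388.23	1.000000	0.000000
8682.17	1.000000	0.000000
8986.41	1.000000	0.000000
9301.32	1.000000	0.000000
9627.26	1.000000	0.000000
9964.62	1.000000	0.000000
10313.81	1.000000	0.000000
10675.23	1.000000	0.000000
11049.31	1.000000	0.000000
11436.51	1.000000	0.000000
11837.27	1.000000	0.000000
12252.08	1.000000	0.000000
12681.42	1.000000	0.000000
13125.80	1.000000	0.000000
13585.76	1.000000	0.000000
14061.84	1.000000	0.000000
14554.60	1.000000	0.000000
15064.63	1.000000	0.000000
15592.53	1.000000	0.000000
16138.93	1.000000	0.000000
16704.48	1.000000	0.000000
17289.84	1.000000	0.000000
17895.72	1.000000	0.000000
18522.83	1.000000	0.000000
19171.91	1.000000	0.000000
19843.74	1.000000	0.000000
20539.12	1.000000	0.000000
21258.86	1.000000	0.000000
22003.82	1.000000	0.000000
22774.88	1.000000	0.000000
23572.97	1.000000	0.000000
24399.02	1.000000	0.000000
25254.02	1.000000	0.000000
26138.98	1.000000	0.000000
27054.96	1.000000	0.000000
28003.03	1.000000	0.000000
28984.32	1.000000	0.000000
30000.00	1.000000	0.000000
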