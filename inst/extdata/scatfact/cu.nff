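# Cu Z=29 f1 f2 vs photon energy (eV); Cromer-Liberman, f1 = Z + f'
E(eV)	f1	f2
250.00	18.635405	7.463512
258.76	18.788942	7.353877
267.83	18.937383	7.241441
277.21	19.080538	7.126218
286.93	19.218190	7.008224
296.98	19.869194	6.874988
307.39	19.984438	6.703767
318.16	20.089529	6.532452
329.31	20.184472	6.361313
340.85	20.269266	6.190608
352.79	20.343891	6.020584
365.16	20.408300	5.851473
377.95	20.462415	5.683497
391.20	20.506123	5.516863
404.91	20.539269	5.351765
419.09	20.561649	5.188386
433.78	20.572995	5.026896
448.98	20.572970	4.867452
464.71	20.561145	4.710199
481.00	20.556478	4.555069
497.85	20.518213	4.400859
515.30	20.466032	4.249426
533.36	20.398909	4.100863
552.05	20.315571	3.955253
571.39	20.214414	3.812666
591.42	20.093407	3.673165
612.14	19.949962	3.536801
633.59	19.780745	3.403618
655.79	19.581404	3.273649
678.78	19.346177	3.146920
702.56	19.067281	3.023449
727.18	18.822507	2.903239
752.66	18.407869	2.784658
779.04	17.898068	2.669957
806.34	17.262486	2.559022
834.59	16.443891	2.451746
863.84	15.341505	2.348026
894.11	13.758519	2.247765
925.44	11.247892	2.150872
957.87	9.966775	17.699928
991.44	16.300693	16.266841
1026.18	18.311624	15.015708
1062.14	19.436693	14.178663
1099.36	19.552100	15.011925
1137.88	21.841624	14.497623
1177.76	23.285976	13.869974
1219.03	24.245976	13.216361
1261.75	25.022893	12.589052
1305.96	25.668792	11.987203
1351.73	26.213735	11.409986
1399.09	26.700068	10.856172
1448.12	27.106944	10.322860
1498.87	27.444288	9.810429
1551.39	27.733242	9.320454
1605.76	27.978683	8.852356
1662.03	28.191480	8.405040
1720.27	28.371940	7.977795
1780.55	28.525060	7.569883
1842.94	28.654161	7.180579
1907.52	28.762095	6.809175
1974.37	28.851327	6.454981
2043.56	28.924007	6.117324
2115.17	28.982016	5.795551
2189.29	29.026940	5.489027
2266.01	29.063145	5.196698
2345.41	29.085886	4.918505
2427.60	29.099509	4.653892
2512.67	29.105052	4.402287
2600.72	29.103440	4.163133
2691.85	29.095497	3.935894
2786.18	29.081957	3.720051
2883.82	29.063471	3.515100
2984.87	29.040619	3.320559
3089.47	29.013531	3.134885
3197.73	28.982836	2.958857
3309.79	28.949052	2.792206
3425.77	28.912579	2.634465
3545.82	28.873758	2.485191
3670.07	28.832867	2.343961
3798.68	28.795750	2.210065
3931.80	28.753805	2.083011
4069.58	28.707069	1.962987
4212.18	28.658987	1.849631
4359.79	28.609622	1.742588
4512.57	28.558995	1.641520
4670.70	28.507077	1.546106
4834.37	28.456869	1.455877
5003.78	28.401804	1.370599
5179.12	28.345041	1.290163
5360.61	28.286313	1.214305
5548.46	28.225263	1.142772
5742.89	28.161417	1.075326
5944.14	28.094153	1.011743
6152.43	28.022651	0.951807
6368.03	27.945815	0.895316
6591.18	27.862162	0.842079
6822.15	27.769625	0.791913
7061.22	27.665240	0.744648
7308.66	27.544564	0.700119
7564.77	27.400554	0.658174
7829.86	27.221126	0.618667
8104.23	26.983049	0.581460
8388.23	26.632587	0.546423
8682.17	25.990894	0.513432
8986.41	22.186184	3.896247
9301.32	26.436300	3.642910
9627.26	27.208672	3.437097
9964.62	27.692658	3.255253
10313.81	28.032200	3.081795
10675.23	28.288337	2.916407
11049.31	28.489355	2.758781
11436.51	28.650915	2.608616
11837.27	28.787495	2.464951
12252.08	28.895247	2.327504
12681.42	28.984127	2.197061
13125.80	29.057619	2.073305
13585.76	29.118373	1.955928
14061.84	29.168462	1.844638
14554.60	29.209541	1.739151
15064.63	29.242954	1.639197
15592.53	29.269811	1.544515
16138.93	29.291039	1.454856
16704.48	29.307419	1.369981
17289.84	29.319616	1.289660
17895.72	29.328547	1.213666
18522.83	29.335990	1.141440
19171.91	29.338373	1.073210
19843.74	29.338434	1.008813
20539.12	29.336512	0.948047
21258.86	29.332898	0.890723
22003.82	29.327849	0.836658
22774.88	29.321586	0.785682
23572.97	29.314435	0.737627
24399.02	29.306270	0.692337
25254.02	29.297414	0.649669
26138.98	29.287999	0.609480
27054.96	29.278143	0.571563
28003.03	29.267914	0.535782
28984.32	29.257403	0.502145
30000.00	29.246702	0.470531
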