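# Fe Z=26 f1 f2 vs photon energy (eV); Cromer-Liberman, f1 = Z + f'
E(eV)	f1	f2
250.00	15.651725	4.750779
258.76	15.732162	4.644117
267.83	15.805992	4.537803
277.21	15.873039	4.431890
286.93	15.933085	4.326433
296.98	15.985872	4.221485
307.39	16.031090	4.117099
318.16	16.068375	4.013329
329.31	16.097300	3.910229
340.85	16.117360	3.807852
352.79	16.127962	3.706250
365.16	16.128404	3.605478
377.95	16.139227	3.504592
391.20	16.115699	3.403760
404.91	16.078895	3.304110
419.09	16.027396	3.205690
433.78	15.959460	3.108545
448.98	15.872936	3.012719
464.71	15.765128	2.918256
481.00	15.632620	2.825199
497.85	15.471012	2.733587
515.30	15.274530	2.643459
533.36	15.035439	2.554854
552.05	14.743111	2.467806
571.39	14.382489	2.382349
591.42	13.931450	2.298514
612.14	13.355975	2.216330
633.59	12.600658	2.135825
655.79	11.568231	2.057024
678.78	10.069557	1.979948
702.56	7.678011	1.904618
727.18	6.207416	16.107394
752.66	11.816750	15.329917
779.04	14.387714	14.585199
806.34	16.006231	13.872108
834.59	17.045585	13.189540
863.84	17.961853	14.307928
894.11	19.431375	13.656864
925.44	20.464984	13.032548
957.87	21.288330	12.434027
991.44	21.970804	11.860375
1026.18	22.571386	11.315321
1062.14	23.066790	10.791665
1099.36	23.495284	10.287688
1137.88	23.867368	9.802936
1177.76	24.191203	9.336949
1219.03	24.530090	8.885801
1261.75	24.770180	8.447443
1305.96	24.978479	8.028102
1351.73	25.158649	7.627111
1399.09	25.314458	7.243819
1448.12	25.460118	6.876919
1498.87	25.578848	6.525486
1551.39	25.693965	6.190122
1605.76	26.003759	5.870219
1662.03	25.704165	5.565181
1720.27	25.798059	5.274429
1780.55	25.848813	4.997412
1842.94	25.883403	4.733575
1907.52	25.906657	4.482377
1974.37	25.920805	4.243300
2043.56	25.927228	4.015842
2115.17	25.926949	3.799514
2189.29	25.920794	3.593843
2266.01	25.909459	3.398373
2345.41	25.893543	3.212662
2427.60	25.873570	3.036280
2512.67	25.849995	2.868815
2600.72	25.823217	2.709869
2691.85	25.793584	2.559057
2786.18	25.761397	2.416008
2883.82	25.727726	2.280344
2984.87	25.690399	2.151774
3089.47	25.654253	2.029054
3197.73	25.614381	1.912907
3309.79	25.572033	1.803166
3425.77	25.532200	1.699345
3545.82	25.485989	1.601042
3670.07	25.438168	1.508237
3798.68	25.388726	1.420635
3931.80	25.337574	1.337957
4069.58	25.284551	1.259937
4212.18	25.229416	1.186321
4359.79	25.171838	1.116871
4512.57	25.111372	1.051359
4670.70	25.047432	0.989570
4834.37	24.979240	0.931300
5003.78	24.905764	0.876354
5179.12	24.825602	0.824550
5360.61	24.736822	0.775714
5548.46	24.636664	0.729680
5742.89	24.521041	0.686294
5944.14	24.383560	0.645407
6152.43	24.213479	0.606880
6368.03	23.990772	0.570580
6591.18	23.671475	0.536384
6822.15	23.125054	0.504172
7061.22	21.361010	0.473832
7308.66	23.071377	3.741268
7564.77	24.012771	3.520315
7829.86	24.560168	3.337816
8104.23	24.936230	3.162344
8388.23	25.217490	2.993785
8682.17	25.437304	2.832017
8986.41	25.612920	2.676695
9301.32	25.752830	2.528319
9627.26	25.868780	2.387860
9964.62	25.964504	2.254541
10313.81	26.043802	2.128039
10675.23	26.109539	2.008041
11049.31	26.163943	1.894248
11436.51	26.208784	1.786372
11837.27	26.245496	1.684137
12252.08	26.275260	1.587279
12681.42	26.299058	1.495543
13125.80	26.317716	1.408685
13585.76	26.332595	1.326458
14061.84	26.342894	1.248638
14554.60	26.353256	1.174607
15064.63	26.356975	1.104491
15592.53	26.358200	1.038312
16138.93	26.357935	0.975848
16704.48	26.355122	0.916907
17289.84	26.350761	0.861320
17895.72	26.345088	0.808911
18522.83	26.338310	0.759510
19171.91	26.330610	0.712954
19843.74	26.322148	0.669092
20539.12	26.313064	0.627777
21258.86	26.303482	0.588871
22003.82	26.293510	0.552243
22774.88	26.283242	0.517768
23572.97	26.272764	0.485327
24399.02	26.262147	0.454809
25254.02	26.251456	0.426105
26138.98	26.240746	0.399116
27054.96	26.230064	0.373696
28003.03	26.219435	0.349756
28984.32	26.208896	0.327292
30000.00	26.198486	0.306218
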