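genotype	group	published_lnor	n_gpos_case	n_gpos_ctrl	n_gneg_case	n_gneg_ctrl
DQA1*01:02-DQB1*06:02	whole	-3.91	26	729	2984	1681
DQA1*01:02-DQB1*06:02	high	-3.12	15	279	1072	882
DQA1*01:02-DQB1*06:02	low	-4.58	11	450	1912	799
DQA1*02:01-DQB1*03:03	whole	-2.21	12	85	2998	2325
DQA1*02:01-DQB1*03:03	high	-2.25	5	49	1082	1112
DQA1*02:01-DQB1*03:03	low	-2.09	7	36	1916	1213
DQA1*01:02-DQB1*05:01	whole	-2.32	14	109	2996	2301
DQA1*01:02-DQB1*05:01	high	-1.80	7	44	1080	1117
DQA1*01:02-DQB1*05:01	low	-2.71	7	65	1916	1184
DRB1*07:01-DQA1*02:01-DQB1*05:01	whole	-1.69	12	52	2998	2358
DRB1*07:01-DQA1*02:01-DQB1*05:01	high	-1.13	9	29	1078	1132
DRB1*07:01-DQA1*02:01-DQB1*05:01	low	-2.45	3	23	1920	1226
DQA1*01:02	whole	-1.91	252	922	2758	1488
DQA1*01:02	high	-1.63	88	359	999	802
DQA1*01:02	low	-2.18	164	563	1759	686
DQA1*05:05-DQB1*03:01	whole	-1.74	88	355	2922	2055
DQA1*05:05-DQB1*03:01	high	-1.39	53	198	1034	963
DQA1*05:05-DQB1*03:01	low	-2.05	35	157	1888	1092
DQA1*01:03	whole	-1.75	67	279	2943	2131
DQA1*01:03	high	-1.54	35	156	1052	1005
DQA1*01:03	low	-1.86	32	123	1891	1126
DQA1*02:01	whole	-1.15	256	548	2754	1862
DQA1*02:01	high	-0.88	149	322	938	839
DQA1*02:01	low	-1.32	107	226	1816	1023
DQB1*03:01	whole	-1.25	361	777	2649	1633
DQB1*03:01	high	-0.85	269	505	818	656
DQB1*03:01	low	-1.71	92	272	1831	977
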