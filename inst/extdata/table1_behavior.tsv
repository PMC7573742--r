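subject_id	gts_hp	imi_hp	lh_grip	rh_grip	months_post	lesion_volume	education	gender	age
1	0.60	0.70	22.34	20.34	174	115118	16	F	54
2	0.75	0.50	35	NA	172	258736	18	M	68
3	1.00	0.90	NA	NA	7	16978	12	M	31
4	0.83	0.90	37.67	27	112	166393	13	M	57
5	0.63	0.60	14.67	15	7	20190	12	F	69
6	0.73	0.70	30	20	14	76301	18	M	64
7	0.55	0.00	27.34	NA	22	171128	18	M	51
8	0.84	0.90	30.67	33	89	51780	21	M	79
9	0.80	0.60	20.67	16	47	82964	14	M	53
10	0.60	0.70	15	14	4	33183	14	F	59
11	0.93	0.70	17	13	73	37091	14	F	55
12	0.54	0.28	13.34	15.34	114	18528	12	F	80
13	0.83	0.50	26.34	NA	84	80020	13	F	47
14	0.88	0.70	47.67	37.34	24	47442	12	M	53
15	0.62	0.60	39.67	NA	31	179606	15	M	57
16	0.68	0.70	31	33	6	23141	12	M	55
17	1.00	0.60	37.67	31.67	53	20105	21	M	56
18	0.79	0.70	17.67	NA	8	71022	16	F	60
19	0.56	0.40	14.67	22	9	62204	18	F	32
20	0.93	0.50	24.34	29.67	68	94536	12	F	45
21	0.24	0.50	8	NA	11	303310	12	F	65
22	0.50	0.40	23.34	28	7	61198	12	F	71
23	0.66	0.70	28.34	NA	32	136576	12	F	46
24	0.75	0.90	33.34	26	24	52416	14	M	48
25	0.83	0.70	18	22	9	128897	12	F	54
26	0.76	0.90	35.67	34	7	51399	18	M	62
27	0.76	0.80	NA	NA	7	20790	12	F	50
28	0.85	0.70	41	NA	10	88046	13	M	31
29	0.90	0.70	33.34	4.34	65	27840	12	F	39
30	0.83	0.78	29	16	6	92744	12	M	48
31	0.70	0.70	NA	NA	31	200079	12	M	61
32	0.63	0.50	26.67	8.67	19	117809	12	F	41
33	0.79	0.40	22	24.67	40	5953	16	M	64
34	0.70	0.30	22.67	22.67	9	32684	13	F	64
35	0.95	0.40	46.34	54	32	337	16	M	55
36	0.55	0.90	28	30.34	31	32003	18	M	71
37	0.95	0.60	36	14.34	23	4095	18	M	63
38	0.87	0.70	42.34	14	10	27004	12	M	48
39	0.76	0.90	26.34	34	20	29052	12	M	58
40	0.87	0.40	31.34	35.67	17	102522	16	F	38
41	0.90	0.70	34.34	22.34	16	14660	18	M	53
42	0.80	0.70	21.67	20	4	9489	12	F	68
43	0.85	0.40	35.67	0	63	44493	18	F	46
44	0.89	0.90	19.67	17.67	17	16977	9	M	50
45	0.89	0.80	23.67	17.34	6	30414	12	F	68
46	0.65	0.60	NA	NA	7	16186	14	F	70
47	0.98	1.00	46	53.34	6	64375	12	M	45
48	0.74	0.60	26.67	0	9	56281	9	F	66
49	0.39	0.40	29.34	NA	12	225021	16	M	64
50	0.88	0.78	26	7.67	71	48459	13	F	53
51	0.90	0.86	NA	NA	17	93628	16	F	37
52	0.82	0.90	21.67	27.67	12	1869	12	F	67
53	0.98	0.80	36.67	32.34	12	17706	12	M	51
54	0.89	0.71	37.34	33.34	151	80532	16	F	55
55	0.85	0.78	30.67	NA	184	62530	13	F	60
56	0.87	0.64	23.67	10	30	87120	18	M	76
57	0.80	0.50	45.34	NA	161	96196	13	M	60
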