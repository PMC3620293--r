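0	34
1	33.8108108108108
2	33.6216216216216
3	33.4324324324324
4	33.2432432432432
5	33.0540540540541
6	32.8648648648649
7	32.6756756756757
8	32.4864864864865
9	32.2972972972973
10	32.1081081081081
11	31.9189189189189
12	31.7297297297297
13	31.5405405405405
14	31.3513513513514
15	31.1621621621622
16	30.972972972973
17	30.7837837837838
18	30.5945945945946
19	30.4054054054054
20	30.2162162162162
21	30.027027027027
22	29.8378378378378
23	29.6486486486486
24	29.4594594594595
25	29.2702702702703
26	29.0810810810811
27	28.8918918918919
28	28.7027027027027
29	28.5135135135135
30	28.3243243243243
31	28.1351351351351
32	27.9459459459459
33	27.7567567567568
34	27.5675675675676
35	27.3783783783784
36	27.1891891891892
37	27
38	26.8108108108108
39	26.6216216216216
40	26.4324324324324
41	26.2432432432432
42	26.0540540540541
43	25.8648648648649
44	25.6756756756757
45	25.4864864864865
46	25.2972972972973
47	25.1081081081081
48	24.9189189189189
49	24.7297297297297
50	24.5405405405405
51	24.3513513513514
52	24.1621621621622
53	23.972972972973
54	23.7837837837838
55	23.5945945945946
56	23.4054054054054
57	23.2162162162162
58	23.027027027027
59	22.8378378378378
60	22.6486486486486
61	22.4594594594595
62	22.2702702702703
63	22.0810810810811
64	21.8918918918919
65	21.7027027027027
66	21.5135135135135
67	21.3243243243243
68	21.1351351351351
69	20.9459459459459
70	20.7567567567568
71	20.5675675675676
72	20.3783783783784
73	20.1891891891892
74	20
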