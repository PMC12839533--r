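age	q
0	0.00054744785094096304
1	0.00055192787147817501
2	0.00055682977173310277
3	0.00056219327738871172
4	0.00056806185437074941
5	0.00057448306090623902
6	0.00058150893270170201
7	0.00058919640435350917
8	0.00059760777039485902
9	0.00060681118970118408
10	0.00061688123732639433
11	0.00062789950822295104
12	0.0006399552777129891
13	0.00065314622403733757
14	0.00066757921880333804
15	0.00068337119169592508
16	0.00070065007641217925
17	0.00071955584542737761
18	0.0007402416419066693
19	0.00076287501785388123
20	0.00078763928842906505
21	0.00081473501329143438
22	0.00084438161682687252
23	0.00087681916021820072
24	0.0009123102795115523
25	0.00095114230513637654
26	0.00099362957975912547
27	0.0010401159928957737
28	0.0010909777523994135
29	0.0011466264147692584
30	0.0012075121982275672
31	0.0012741276046790428
32	0.001347011379026819
33	0.0014267528368800964
34	0.001513996594464051
35	0.0016094477375573346
36	0.0017138774695403258
37	0.0018281292821650252
38	0.0019531256964701038
39	0.0020898756253742157
40	0.0022394824139099212
41	0.002403152617828086
42	0.0025822055864107574
43	0.0027780839208110253
44	0.0029923648850888052
45	0.003226772853344162
46	0.0034831928829700542
47	0.0037636855110501077
48	0.0040705028782990205
49	0.0044061062926787908
50	0.0047731853528639734
51	0.005174678760062279
52	0.0056137969552142453
53	0.0060940467272492249
54	0.0066192579467072576
55	0.0071936125875212698
56	0.0078216762078762159
57	0.008508432068578875
58	0.0092593180739684033
59	0.0100802667256914
60	0.010977748283166666
61	0.011958817325703475
62	0.013031162909293847
63	0.014203162505205147
64	0.015483939896638654
65	0.016883427192613931
66	0.018412431093433601
67	0.020082703507785404
68	0.021907016575671512
69	0.023899242091461215
70	0.026074435244533789
71	0.02844892249790032
72	0.031040393303932823
73	0.033867995206451007
74	0.036952431694787125
75	0.040316061952327731
76	0.04398300137288369
77	0.047979221395973659
78	0.052332646828816443
79	0.057073248370190122
80	0.06223312752051724
81	0.06784659044470065
82	0.073950206640776894
83	0.080582847450610395
84	0.08778569852272522
85	0.095602239298655967
86	0.10407818144413106
87	0.11326135689225258
88	0.12320154482369672
89	0.13395022550645108
90	0.14556024749816943
91	0.15808539334080307
92	0.17157982763834267
93	0.18609741042364147
94	0.20169085814626864
95	0.21841073465092742
96	0.23630425541551037
97	0.25541389038394924
98	0.2757757543207644
99	0.29741777914352918
100	1
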