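position	guide_base	target_base	activity
1	A	C	0.6175
1	A	G	0.76
1	A	T	0.5225
1	C	A	0.665
1	C	G	0.57
1	C	T	0.8075
1	G	A	0.855
1	G	C	0.5225
1	G	T	0.7125
1	T	A	0.57
1	T	C	0.8075
1	T	G	0.9025
2	A	C	0.5884
2	A	G	0.7242
2	A	T	0.4979
2	C	A	0.6337
2	C	G	0.5432
2	C	T	0.7695
2	G	A	0.8148
2	G	C	0.4979
2	G	T	0.679
2	T	A	0.5432
2	T	C	0.7695
2	T	G	0.86
3	A	C	0.5593
3	A	G	0.6884
3	A	T	0.4733
3	C	A	0.6023
3	C	G	0.5163
3	C	T	0.7314
3	G	A	0.7745
3	G	C	0.4733
3	G	T	0.6454
3	T	A	0.5163
3	T	C	0.7314
3	T	G	0.8175
4	A	C	0.5303
4	A	G	0.6526
4	A	T	0.4487
4	C	A	0.5711
4	C	G	0.4895
4	C	T	0.6934
4	G	A	0.7342
4	G	C	0.4487
4	G	T	0.6118
4	T	A	0.4895
4	T	C	0.6934
4	T	G	0.775
5	A	C	0.5012
5	A	G	0.6169
5	A	T	0.4241
5	C	A	0.5398
5	C	G	0.4627
5	C	T	0.6554
5	G	A	0.694
5	G	C	0.4241
5	G	T	0.5783
5	T	A	0.4627
5	T	C	0.6554
5	T	G	0.7325
6	A	C	0.4721
6	A	G	0.581
6	A	T	0.3995
6	C	A	0.5084
6	C	G	0.4358
6	C	T	0.6174
6	G	A	0.6537
6	G	C	0.3995
6	G	T	0.5447
6	T	A	0.4358
6	T	C	0.6174
6	T	G	0.69
7	A	C	0.443
7	A	G	0.5453
7	A	T	0.3749
7	C	A	0.4771
7	C	G	0.409
7	C	T	0.5794
7	G	A	0.6134
7	G	C	0.3749
7	G	T	0.5112
7	T	A	0.409
7	T	C	0.5794
7	T	G	0.6475
8	A	C	0.4139
8	A	G	0.5094
8	A	T	0.3502
8	C	A	0.4458
8	C	G	0.3821
8	C	T	0.5413
8	G	A	0.5731
8	G	C	0.3502
8	G	T	0.4776
8	T	A	0.3821
8	T	C	0.5413
8	T	G	0.605
9	A	C	0.3849
9	A	G	0.4737
9	A	T	0.3257
9	C	A	0.4145
9	C	G	0.3553
9	C	T	0.5033
9	G	A	0.5329
9	G	C	0.3257
9	G	T	0.4441
9	T	A	0.3553
9	T	C	0.5033
9	T	G	0.5625
10	A	C	0.3558
10	A	G	0.4379
10	A	T	0.3011
10	C	A	0.3832
10	C	G	0.3284
10	C	T	0.4653
10	G	A	0.4927
10	G	C	0.3011
10	G	T	0.4105
10	T	A	0.3284
10	T	C	0.4653
10	T	G	0.52
11	A	C	0.3267
11	A	G	0.4021
11	A	T	0.2764
11	C	A	0.3518
11	C	G	0.3016
11	C	T	0.4272
11	G	A	0.4523
11	G	C	0.2764
11	G	T	0.377
11	T	A	0.3016
11	T	C	0.4272
11	T	G	0.4775
12	A	C	0.2976
12	A	G	0.3663
12	A	T	0.2518
12	C	A	0.3205
12	C	G	0.2747
12	C	T	0.3892
12	G	A	0.4121
12	G	C	0.2518
12	G	T	0.3434
12	T	A	0.2747
12	T	C	0.3892
12	T	G	0.435
13	A	C	0.2686
13	A	G	0.3306
13	A	T	0.2273
13	C	A	0.2892
13	C	G	0.2479
13	C	T	0.3512
13	G	A	0.3719
13	G	C	0.2273
13	G	T	0.3099
13	T	A	0.2479
13	T	C	0.3512
13	T	G	0.3925
14	A	C	0.2395
14	A	G	0.2947
14	A	T	0.2026
14	C	A	0.2579
14	C	G	0.221
14	C	T	0.3131
14	G	A	0.3316
14	G	C	0.2026
14	G	T	0.2763
14	T	A	0.221
14	T	C	0.3131
14	T	G	0.35
15	A	C	0.2104
15	A	G	0.259
15	A	T	0.178
15	C	A	0.2266
15	C	G	0.1942
15	C	T	0.2751
15	G	A	0.2913
15	G	C	0.178
15	G	T	0.2428
15	T	A	0.1942
15	T	C	0.2751
15	T	G	0.3075
16	A	C	0.1813
16	A	G	0.2231
16	A	T	0.1534
16	C	A	0.1952
16	C	G	0.1673
16	C	T	0.2371
16	G	A	0.251
16	G	C	0.1534
16	G	T	0.2092
16	T	A	0.1673
16	T	C	0.2371
16	T	G	0.265
17	A	C	0.1522
17	A	G	0.1874
17	A	T	0.1288
17	C	A	0.1639
17	C	G	0.1405
17	C	T	0.1991
17	G	A	0.2108
17	G	C	0.1288
17	G	T	0.1756
17	T	A	0.1405
17	T	C	0.1991
17	T	G	0.2225
18	A	C	0.1232
18	A	G	0.1516
18	A	T	0.1042
18	C	A	0.1326
18	C	G	0.1137
18	C	T	0.1611
18	G	A	0.1706
18	G	C	0.1042
18	G	T	0.1421
18	T	A	0.1137
18	T	C	0.1611
18	T	G	0.18
19	A	C	0.0941
19	A	G	0.1158
19	A	T	0.0796
19	C	A	0.1013
19	C	G	0.0868
19	C	T	0.123
19	G	A	0.1302
19	G	C	0.0796
19	G	T	0.1085
19	T	A	0.0868
19	T	C	0.123
19	T	G	0.1375
20	A	C	0.065
20	A	G	0.08
20	A	T	0.055
20	C	A	0.07
20	C	G	0.06
20	C	T	0.085
20	G	A	0.09
20	G	C	0.055
20	G	T	0.075
20	T	A	0.06
20	T	C	0.085
20	T	G	0.095
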