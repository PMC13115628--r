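age,qx
0,0.000467
1,0.000473
2,0.000479
3,0.000486
4,0.000494
5,0.000502
6,0.000511
7,0.000521
8,0.000532
9,0.000543
10,0.000556
11,0.00057
12,0.000585
13,0.000601
14,0.000619
15,0.000639
16,0.00066
17,0.000683
18,0.000708
19,0.000735
20,0.000765
21,0.000798
22,0.000833
23,0.000871
24,0.000913
25,0.000958
26,0.001008
27,0.001062
28,0.001121
29,0.001185
30,0.001254
31,0.00133
32,0.001413
33,0.001502
34,0.0016
35,0.001707
36,0.001823
37,0.001949
38,0.002086
39,0.002236
40,0.002399
41,0.002576
42,0.002769
43,0.002979
44,0.003208
45,0.003457
46,0.003728
47,0.004024
48,0.004345
49,0.004695
50,0.005076
51,0.005491
52,0.005943
53,0.006434
54,0.00697
55,0.007552
56,0.008187
57,0.008878
58,0.00963
59,0.010449
60,0.01134
61,0.012311
62,0.013368
63,0.014518
64,0.01577
65,0.017134
66,0.018619
67,0.020235
68,0.021995
69,0.023911
70,0.025996
71,0.028267
72,0.030739
73,0.033431
74,0.036362
75,0.039552
76,0.043025
77,0.046807
78,0.050924
79,0.055406
80,0.060286
81,0.065599
82,0.071384
83,0.077681
84,0.084537
85,0.092002
86,0.100128
87,0.108976
88,0.118608
89,0.129096
90,0.140513
91,0.152943
92,0.166477
93,0.181211
94,0.197252
95,0.214716
96,0.233729
97,0.254429
98,0.276966
99,0.301502
100,0.328215
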