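# Two-point IC50 estimates (uM) reported for the 66 assayed virtual hit
# candidates; empty ic50_uM marks "n.i." (no inhibition).
compound,ic50_uM
1,51.4
2,42.0
3,71.2
4,13.4
5,33.5
6,40.5
7,18.7
8,20.2
9,46.2
10,11.3
11,5.08
12,19.6
13,5.34
14,58.2
15,23.4
16,174
17,93.9
18,122
19,33.9
20,188
21,37.9
22,68.3
23,194
24,168
25,
26,115
27,26.6
28,15.3
29,9.74
30,20.4
31,
32,9.89
33,58.2
34,
35,121
36,92.5
37,212
38,66.3
39,50.0
40,54.6
41,17.1
42,29.4
43,73.4
44,29.6
45,59.6
46,74.3
47,21.5
48,127
49,117
50,13.3
51,61.3
52,207
53,123
54,28.5
55,23.4
56,98.0
57,35.5
58,12.6
59,9.12
60,62.2
61,33.1
62,59.6
63,87.4
64,49.5
65,41.4
66,60.7
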