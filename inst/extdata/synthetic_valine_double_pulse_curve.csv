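"time_min","percent_germinated"
0,0
1,0.6
2,0.6
3,0.6
4,1.3
5,1.3
6,1.3
7,1.3
8,1.3
9,1.3
10,1.3
11,1.3
12,2.2
13,2.2
14,5.7
15,9.7
16,11.2
17,11.4
18,13.4
19,13.4
20,14.5
21,14.5
22,15.2
23,15.2
24,15.2
25,15.2
26,15.2
27,15.2
28,15.6
29,15.6
30,15.6
31,15.6
32,15.6
33,15.6
34,15.6
35,15.6
36,15.6
37,15.6
38,19.9
39,29
40,43
41,46.8
42,52.2
43,58.6
44,63.9
45,65.1
46,67.2
47,67.2
48,67.2
49,67.3
50,67.3
51,67.3
52,67.3
53,67.9
54,67.9
55,67.9
56,67.9
57,68.1
58,68.1
59,68.1
60,68.1
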