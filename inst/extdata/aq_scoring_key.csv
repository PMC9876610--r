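"item","agree_keyed"
1,0
2,1
3,0
4,1
5,1
6,1
7,1
8,0
9,1
10,0
11,0
12,1
13,1
14,0
15,0
16,1
17,0
18,1
19,1
20,1
21,1
22,1
23,1
24,0
25,0
26,1
27,0
28,0
29,0
30,0
31,0
32,0
33,1
34,0
35,1
36,0
37,0
38,0
39,1
40,0
41,1
42,1
43,1
44,0
45,1
46,1
47,0
48,0
49,0
50,0
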