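position,residue
1,S
2,Y
3,E
4,L
5,T
6,Q
7,P
8,P
9,S
11,V
12,S
13,V
14,S
15,P
16,G
17,Q
18,T
19,A
20,S
21,I
22,T
23,C
24,S
25,G
26,D
27,S
28,L
29,G
30,S
31,Y
32,F
33,V
34,H
35,W
36,Y
37,Q
38,Q
39,K
40,P
41,G
42,Q
43,S
44,P
45,V
46,L
47,V
48,I
49,Y
50,D
51,D
52,S
53,N
54,R
55,P
56,S
57,G
58,I
59,P
60,E
61,R
62,F
63,S
64,G
65,S
66,N
67,S
68,G
69,N
70,T
71,A
72,T
73,L
74,T
75,I
76,S
77,G
78,T
79,Q
80,A
81,M
82,D
83,E
84,A
85,D
86,Y
87,Y
88,C
89,S
90,A
91,F
92,T
93,H
94,N
95,S
96,D
97,V
98,F
99,G
100,G
101,G
102,T
103,K
104,L
105,T
106,V
107,L
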