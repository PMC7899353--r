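pacer_laps_20m,pacer_score
18,3
31,6
169,10
38,7
63,10
12,2
25,5
110,10
33,6
NA,NA
127,10
62,10
39,7
19,3
NA,NA
84,10
145,10
166,10
108,10
125,10
98,10
147,10
85,10
49,9
4,0
118,10
144,10
85,10
122,10
85,10
197,10
5,1
184,10
19,3
63,10
112,10
89,10
46,9
178,10
35,7
69,10
122,10
54,10
79,10
120,10
85,10
1,0
187,10
59,10
178,10
47,9
55,10
89,10
98,10
79,10
119,10
11,2
70,10
89,10
88,10
68,10
82,10
116,10
38,7
152,10
195,10
4,0
69,10
100,10
99,10
NA,NA
88,10
57,10
43,8
98,10
125,10
127,10
5,1
16,3
173,10
20,4
33,6
89,10
99,10
39,7
35,7
43,8
100,10
177,10
15,3
141,10
141,10
39,7
NA,NA
8,1
41,8
43,8
2,0
101,10
NA,NA
54,10
78,10
90,10
176,10
40,8
2,0
122,10
58,10
98,10
5,1
51,10
112,10
101,10
122,10
12,2
177,10
38,7
92,10
31,6
53,10
102,10
200,10
138,10
166,10
62,10
31,6
86,10
75,10
87,10
56,10
147,10
140,10
45,9
51,10
136,10
74,10
148,10
194,10
67,10
142,10
172,10
121,10
NA,NA
78,10
40,8
18,3
59,10
190,10
78,10
69,10
33,6
78,10
78,10
58,10
84,10
122,10
27,5
199,10
147,10
75,10
180,10
84,10
36,7
129,10
14,2
133,10
70,10
65,10
8,1
43,8
110,10
64,10
69,10
120,10
125,10
28,5
142,10
115,10
108,10
14,2
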