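state,RF,ESR1h,PtVAS,DrVAS,STAGE,SJC28,TJC28,energy,next_state,minimal_state
1,-1,-1,-1,-1,-1,-1,-1,-2.7629,65,81
2,-1,-1,-1,-1,-1,-1,1,0.098937,1,81
3,-1,-1,-1,-1,-1,1,-1,-0.19946,1,81
4,-1,-1,-1,-1,-1,1,1,1.8936,3,81
5,-1,-1,-1,-1,1,-1,-1,-0.79545,1,81
6,-1,-1,-1,-1,1,-1,1,2.0551,5,81
7,-1,-1,-1,-1,1,1,-1,0.94894,5,81
8,-1,-1,-1,-1,1,1,1,3.0307,7,81
9,-1,-1,-1,1,-1,-1,-1,0.84369,1,81
10,-1,-1,-1,1,-1,-1,1,1.4102,26,128
11,-1,-1,-1,1,-1,1,-1,1.1752,3,81
12,-1,-1,-1,1,-1,1,1,0.97285,28,128
13,-1,-1,-1,1,1,-1,-1,2.2545,5,81
14,-1,-1,-1,1,1,-1,1,2.8096,30,128
15,-1,-1,-1,1,1,1,-1,1.7669,31,128
16,-1,-1,-1,1,1,1,1,1.5532,32,128
17,-1,-1,1,-1,-1,-1,-1,-2.8443,81,81
18,-1,-1,1,-1,-1,-1,1,-0.8946,17,81
19,-1,-1,1,-1,-1,1,-1,-0.39429,17,81
20,-1,-1,1,-1,-1,1,1,0.78658,28,128
21,-1,-1,1,-1,1,-1,-1,-1.4456,17,81
22,-1,-1,1,-1,1,-1,1,0.49277,21,81
23,-1,-1,1,-1,1,1,-1,0.18531,21,81
24,-1,-1,1,-1,1,1,1,1.3548,32,128
25,-1,-1,1,1,-1,-1,-1,-0.37108,17,81
26,-1,-1,1,1,-1,-1,1,-0.71684,90,128
27,-1,-1,1,1,-1,1,-1,-0.15312,28,128
28,-1,-1,1,1,-1,1,1,-1.2677,92,128
29,-1,-1,1,1,1,-1,-1,0.47091,21,81
30,-1,-1,1,1,1,-1,1,0.11382,94,128
31,-1,-1,1,1,1,1,-1,-0.13022,95,128
32,-1,-1,1,1,1,1,1,-1.2561,96,128
33,-1,1,-1,-1,-1,-1,-1,-1.421,1,81
34,-1,1,-1,-1,-1,-1,1,1.484,33,81
35,-1,1,-1,-1,-1,1,-1,0.59228,33,81
36,-1,1,-1,-1,-1,1,1,2.7285,35,81
37,-1,1,-1,-1,1,-1,-1,0.49006,101,81
38,-1,1,-1,-1,1,-1,1,3.3837,37,81
39,-1,1,-1,-1,1,1,-1,1.6842,103,81
40,-1,1,-1,-1,1,1,1,3.8091,39,81
41,-1,1,-1,1,-1,-1,-1,1.6325,33,81
42,-1,1,-1,1,-1,-1,1,2.2421,58,128
43,-1,1,-1,1,-1,1,-1,1.4138,59,128
44,-1,1,-1,1,-1,1,1,1.2546,60,128
45,-1,1,-1,1,1,-1,-1,2.9869,37,81
46,-1,1,-1,1,1,-1,1,3.5851,62,128
47,-1,1,-1,1,1,1,-1,1.949,63,128
48,-1,1,-1,1,1,1,1,1.7785,64,128
49,-1,1,1,-1,-1,-1,-1,-1.8425,113,81
50,-1,1,1,-1,-1,-1,1,0.15031,49,81
51,-1,1,1,-1,-1,1,-1,0.057273,49,81
52,-1,1,1,-1,-1,1,1,1.2813,60,128
53,-1,1,1,-1,1,-1,-1,-0.50023,117,81
54,-1,1,1,-1,1,-1,1,1.4812,118,81
55,-1,1,1,-1,1,1,-1,0.58042,119,81
56,-1,1,1,-1,1,1,1,1.7931,64,128
57,-1,1,1,1,-1,-1,-1,0.077572,49,81
58,-1,1,1,1,-1,-1,1,-0.22506,122,128
59,-1,1,1,1,-1,1,-1,-0.25468,123,128
60,-1,1,1,1,-1,1,1,-1.3261,124,128
61,-1,1,1,1,1,-1,-1,0.86311,125,81
62,-1,1,1,1,1,-1,1,0.54914,126,128
63,-1,1,1,1,1,1,-1,-0.28824,127,128
64,-1,1,1,1,1,1,1,-1.371,128,128
65,1,-1,-1,-1,-1,-1,-1,-3.1347,81,81
66,1,-1,-1,-1,-1,-1,1,-0.34836,65,81
67,1,-1,-1,-1,-1,1,-1,-0.43854,65,81
68,1,-1,-1,-1,-1,1,1,1.579,67,81
69,1,-1,-1,-1,1,-1,-1,-1.8916,65,81
70,1,-1,-1,-1,1,-1,1,0.88338,69,81
71,1,-1,-1,-1,1,1,-1,-0.014557,69,81
72,1,-1,-1,-1,1,1,1,1.9917,71,81
73,1,-1,-1,1,-1,-1,-1,0.15463,65,81
74,1,-1,-1,1,-1,-1,1,0.64557,90,128
75,1,-1,-1,1,-1,1,-1,0.61881,91,128
76,1,-1,-1,1,-1,1,1,0.34096,92,128
77,1,-1,-1,1,1,-1,-1,0.841,69,81
78,1,-1,-1,1,1,-1,1,1.3206,94,128
79,1,-1,-1,1,1,1,-1,0.48609,95,128
80,1,-1,-1,1,1,1,1,0.19691,96,128
81,1,-1,1,-1,-1,-1,-1,-3.1748,81,81
82,1,-1,1,-1,-1,-1,1,-1.3007,81,81
83,1,-1,1,-1,-1,1,-1,-0.59216,81,81
84,1,-1,1,-1,-1,1,1,0.51318,92,128
85,1,-1,1,-1,1,-1,-1,-2.5005,81,81
86,1,-1,1,-1,1,-1,1,-0.63775,85,81
87,1,-1,1,-1,1,1,-1,-0.73698,85,81
88,1,-1,1,-1,1,1,1,0.35703,96,128
89,1,-1,1,1,-1,-1,-1,-1.0189,81,81
90,1,-1,1,1,-1,-1,1,-1.4402,122,128
91,1,-1,1,1,-1,1,-1,-0.66827,92,128
92,1,-1,1,1,-1,1,1,-1.8583,124,128
93,1,-1,1,1,1,-1,-1,-0.90136,85,81
94,1,-1,1,1,1,-1,1,-1.334,96,128
95,1,-1,1,1,1,1,-1,-1.3698,96,128
96,1,-1,1,1,1,1,1,-2.5712,128,128
97,1,1,-1,-1,-1,-1,-1,-2.7062,65,81
98,1,1,-1,-1,-1,-1,1,0.12328,97,81
99,1,1,-1,-1,-1,1,-1,-0.56024,97,81
100,1,1,-1,-1,-1,1,1,1.5004,99,81
101,1,1,-1,-1,1,-1,-1,-1.5196,97,81
102,1,1,-1,-1,1,-1,1,1.2986,101,81
103,1,1,-1,-1,1,1,-1,-0.19272,101,81
104,1,1,-1,-1,1,1,1,1.8566,112,128
105,1,1,-1,1,-1,-1,-1,0.030022,97,81
106,1,1,-1,1,-1,-1,1,0.56409,122,128
107,1,1,-1,1,-1,1,-1,-0.056019,123,128
108,1,1,-1,1,-1,1,1,-0.29074,124,128
109,1,1,-1,1,1,-1,-1,0.65994,101,81
110,1,1,-1,1,1,-1,1,1.1827,126,128
111,1,1,-1,1,1,1,-1,-0.2452,127,128
112,1,1,-1,1,1,1,1,-0.49126,128,128
113,1,1,1,-1,-1,-1,-1,-3.0865,81,81
114,1,1,1,-1,-1,-1,1,-1.1692,113,81
115,1,1,1,-1,-1,1,-1,-1.054,113,81
116,1,1,1,-1,-1,1,1,0.094419,124,128
117,1,1,1,-1,1,-1,-1,-2.4687,113,81
118,1,1,1,-1,1,-1,1,-0.56275,117,81
119,1,1,1,-1,1,1,-1,-1.2553,117,81
120,1,1,1,-1,1,1,1,-0.11819,128,128
121,1,1,1,1,-1,-1,-1,-1.4837,113,81
122,1,1,1,1,-1,-1,1,-1.8619,124,128
123,1,1,1,1,-1,1,-1,-1.6833,124,128
124,1,1,1,1,-1,1,1,-2.8302,128,128
125,1,1,1,1,1,-1,-1,-1.4226,117,81
126,1,1,1,1,1,-1,1,-1.8121,128,128
127,1,1,1,1,1,1,-1,-2.4413,128,128
128,1,1,1,1,1,1,1,-3.5995,128,128
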