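position	weight
7	1
9	1
24	1
34	1
45	1
63	1
66	1
67	1
70	1
76	1
77	1
78	1
79	1
80	1
81	1
82	1
83	1
84	1
85	1
93	1
94	1
95	1
99	1
114	1
115	1
116	1
121	1
122	1
123	1
141	1
142	1
143	1
144	1
145	1
146	1
147	1
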