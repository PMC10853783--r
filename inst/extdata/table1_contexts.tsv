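id	minus3	minus2	minus1	plus4	kozak	bacs	tested
1	A	A	A	A	moderate	FALSE	TRUE
2	A	A	A	C	moderate	FALSE	TRUE
3	A	A	A	U	moderate	FALSE	TRUE
4	A	A	A	G	strong	FALSE	TRUE
5	C	A	A	A	weak	FALSE	TRUE
6	C	A	A	C	weak	FALSE	TRUE
7	C	A	A	U	weak	FALSE	TRUE
8	C	A	A	G	moderate	FALSE	TRUE
9	U	A	A	A	weak	FALSE	TRUE
10	U	A	A	C	weak	FALSE	TRUE
11	U	A	A	U	weak	FALSE	TRUE
12	U	A	A	G	moderate	FALSE	TRUE
13	G	A	A	A	moderate	FALSE	TRUE
14	G	A	A	C	moderate	FALSE	TRUE
15	G	A	A	U	moderate	FALSE	TRUE
16	G	A	A	G	strong	FALSE	TRUE
17	A	C	A	A	moderate	FALSE	TRUE
18	A	C	A	C	moderate	FALSE	TRUE
19	A	C	A	U	moderate	FALSE	TRUE
20	A	C	A	G	strong	FALSE	TRUE
21	C	C	A	A	weak	FALSE	TRUE
22	C	C	A	C	weak	FALSE	TRUE
23	C	C	A	U	weak	TRUE	TRUE
24	C	C	A	G	moderate	FALSE	FALSE
25	U	C	A	A	weak	FALSE	TRUE
26	U	C	A	C	weak	FALSE	TRUE
27	U	C	A	U	weak	FALSE	TRUE
28	U	C	A	G	moderate	FALSE	TRUE
29	G	C	A	A	moderate	FALSE	TRUE
30	G	C	A	C	moderate	FALSE	TRUE
31	G	C	A	U	moderate	FALSE	TRUE
32	G	C	A	G	strong	FALSE	TRUE
33	A	U	A	A	moderate	FALSE	TRUE
34	A	U	A	C	moderate	FALSE	TRUE
35	A	U	A	U	moderate	FALSE	TRUE
36	A	U	A	G	strong	FALSE	TRUE
37	C	U	A	A	weak	FALSE	TRUE
38	C	U	A	C	weak	FALSE	TRUE
39	C	U	A	U	weak	FALSE	TRUE
40	C	U	A	G	moderate	FALSE	TRUE
41	U	U	A	A	weak	FALSE	TRUE
42	U	U	A	C	weak	TRUE	TRUE
43	U	U	A	U	weak	FALSE	TRUE
44	U	U	A	G	moderate	FALSE	TRUE
45	G	U	A	A	moderate	FALSE	TRUE
46	G	U	A	C	moderate	FALSE	TRUE
47	G	U	A	U	moderate	FALSE	TRUE
48	G	U	A	G	strong	FALSE	TRUE
49	A	G	A	A	moderate	FALSE	TRUE
50	A	G	A	C	moderate	FALSE	TRUE
51	A	G	A	U	moderate	FALSE	TRUE
52	A	G	A	G	strong	FALSE	TRUE
53	C	G	A	A	weak	FALSE	FALSE
54	C	G	A	C	weak	FALSE	TRUE
55	C	G	A	U	weak	TRUE	TRUE
56	C	G	A	G	moderate	FALSE	TRUE
57	U	G	A	A	weak	FALSE	TRUE
58	U	G	A	C	weak	FALSE	TRUE
59	U	G	A	U	weak	FALSE	TRUE
60	U	G	A	G	moderate	FALSE	TRUE
61	G	G	A	A	moderate	FALSE	TRUE
62	G	G	A	C	moderate	FALSE	TRUE
63	G	G	A	U	moderate	FALSE	TRUE
64	G	G	A	G	strong	FALSE	TRUE
65	A	A	C	A	moderate	FALSE	TRUE
66	A	A	C	C	moderate	FALSE	TRUE
67	A	A	C	U	moderate	FALSE	TRUE
68	A	A	C	G	strong	FALSE	TRUE
69	C	A	C	A	weak	FALSE	TRUE
70	C	A	C	C	weak	FALSE	FALSE
71	C	A	C	U	weak	FALSE	TRUE
72	C	A	C	G	moderate	FALSE	TRUE
73	U	A	C	A	weak	FALSE	TRUE
74	U	A	C	C	weak	TRUE	TRUE
75	U	A	C	U	weak	FALSE	TRUE
76	U	A	C	G	moderate	FALSE	TRUE
77	G	A	C	A	moderate	FALSE	TRUE
78	G	A	C	C	moderate	FALSE	TRUE
79	G	A	C	U	moderate	FALSE	TRUE
80	G	A	C	G	strong	FALSE	TRUE
81	A	C	C	A	moderate	FALSE	TRUE
82	A	C	C	C	moderate	FALSE	TRUE
83	A	C	C	U	moderate	FALSE	TRUE
84	A	C	C	G	strong	FALSE	FALSE
85	C	C	C	A	weak	FALSE	TRUE
86	C	C	C	C	weak	FALSE	TRUE
87	C	C	C	U	weak	TRUE	TRUE
88	C	C	C	G	moderate	FALSE	FALSE
89	U	C	C	A	weak	FALSE	TRUE
90	U	C	C	C	weak	FALSE	TRUE
91	U	C	C	U	weak	TRUE	TRUE
92	U	C	C	G	moderate	FALSE	TRUE
93	G	C	C	A	moderate	FALSE	TRUE
94	G	C	C	C	moderate	FALSE	TRUE
95	G	C	C	U	moderate	FALSE	FALSE
96	G	C	C	G	strong	FALSE	FALSE
97	A	U	C	A	moderate	FALSE	TRUE
98	A	U	C	C	moderate	FALSE	TRUE
99	A	U	C	U	moderate	FALSE	FALSE
100	A	U	C	G	strong	FALSE	TRUE
101	C	U	C	A	weak	FALSE	TRUE
102	C	U	C	C	weak	FALSE	TRUE
103	C	U	C	U	weak	FALSE	TRUE
104	C	U	C	G	moderate	FALSE	TRUE
105	U	U	C	A	weak	FALSE	TRUE
106	U	U	C	C	weak	FALSE	TRUE
107	U	U	C	U	weak	TRUE	TRUE
108	U	U	C	G	moderate	FALSE	TRUE
109	G	U	C	A	moderate	FALSE	TRUE
110	G	U	C	C	moderate	FALSE	TRUE
111	G	U	C	U	moderate	FALSE	TRUE
112	G	U	C	G	strong	FALSE	FALSE
113	A	G	C	A	moderate	FALSE	TRUE
114	A	G	C	C	moderate	FALSE	TRUE
115	A	G	C	U	moderate	FALSE	TRUE
116	A	G	C	G	strong	FALSE	TRUE
117	C	G	C	A	weak	FALSE	TRUE
118	C	G	C	C	weak	FALSE	TRUE
119	C	G	C	U	weak	FALSE	TRUE
120	C	G	C	G	moderate	FALSE	TRUE
121	U	G	C	A	weak	FALSE	TRUE
122	U	G	C	C	weak	FALSE	TRUE
123	U	G	C	U	weak	FALSE	TRUE
124	U	G	C	G	moderate	FALSE	TRUE
125	G	G	C	A	moderate	FALSE	TRUE
126	G	G	C	C	moderate	FALSE	TRUE
127	G	G	C	U	moderate	FALSE	TRUE
128	G	G	C	G	strong	FALSE	TRUE
129	C	C	G	C	weak	FALSE	TRUE
130	C	C	G	U	weak	FALSE	TRUE
131	C	C	U	C	weak	FALSE	TRUE
132	C	C	U	U	weak	FALSE	TRUE
133	U	C	G	C	weak	FALSE	TRUE
134	U	C	G	U	weak	FALSE	TRUE
135	U	C	U	C	weak	FALSE	TRUE
136	U	C	U	U	weak	FALSE	TRUE
137	C	A	G	C	weak	FALSE	TRUE
138	C	A	G	U	weak	FALSE	TRUE
139	C	A	U	C	weak	FALSE	TRUE
140	C	A	U	U	weak	FALSE	TRUE
141	U	A	G	C	weak	FALSE	TRUE
142	U	A	G	U	weak	FALSE	TRUE
143	U	A	U	C	weak	FALSE	TRUE
144	U	A	U	U	weak	FALSE	TRUE
145	C	U	G	C	weak	FALSE	TRUE
146	C	U	G	U	weak	FALSE	TRUE
147	C	U	U	C	weak	FALSE	TRUE
148	C	U	U	U	weak	FALSE	TRUE
149	U	U	G	C	weak	FALSE	FALSE
150	U	U	G	U	weak	FALSE	TRUE
151	U	U	U	C	weak	FALSE	TRUE
152	U	U	U	U	weak	FALSE	TRUE
153	C	G	G	C	weak	FALSE	TRUE
154	C	G	G	U	weak	FALSE	TRUE
155	C	G	U	C	weak	FALSE	TRUE
156	C	G	U	U	weak	FALSE	TRUE
157	U	G	G	C	weak	FALSE	TRUE
158	U	G	G	U	weak	FALSE	TRUE
159	U	G	U	C	weak	FALSE	TRUE
160	U	G	U	U	weak	TRUE	TRUE
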