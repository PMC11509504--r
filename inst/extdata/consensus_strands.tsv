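position	Ala	Arg	Arg2	Asn	Asp	Cys	Gln	Glu	Gly	His	Ile	Leu	Leu2	LysI	LysII	Met	Phe	Pro	Ser	Ser2	Thr	Trp	Tyr	Val
-1	-	-	-	-	-	-	-	-	-	G	-	-	-	-	-	-	-	-	-	-	-	-	-	-
1	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	C	G	G	G	A	G	G
2	G	G	C	U	A	G	G	C	C	C	G	C	U	G	A	C	C	G	G	A	C	G	G	G
3	G	G	C	C	C	C	U	C	G	C	G	U	C	G	C	C	C	G	A	C	C	G	A	U
4	G	C	C	U	A	U	G	C	G	G	C	A	A	C	U	U	G	C	G	A	G	G	G	U
5	G	C	C	C	C	A	C	U	G	U	C	G	G	C	G	G	A	G	G	A	A	G	G	C
6	C	C	C	U	G	C	C	C	G	U	U	U	G	C	G	C	G	A	C	A	U	C	G	C
7	A	G	G	G	G	A	A	G	G	A	U	A	A	G	U	G	A	G	G	G	U	G	G	G
8	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U
9	A	A	A	K	A	G	K	G	A	A	A	G	G	A	A	A	A	A	G	G	A	A	A	A
10	G	G	G	L	G	G	G	G	G	G	G	L	G	G	L	G	L	G	G	G	G	G	G	G
11	C	C	C	C	U	C	U	U	U	U	C	C	C	C	C	C	C	C	C	C	C	U	C	U
12	U	U	U	G	A	C	G	C	U	U	U	M	M	U	U	U	U	C	M	C	U	U	G	U
13	C	C	U	C	P	G	P	P	U	P	C	G	G	C	C	C	C	C	G	-	C	C	A	P
14	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A
15	G	A	A	A	G	G	G	G	A	G	G	G	G	G	G	G	G	G	G	G	G	A	G	G
16	C	D	U	D	U	C	D	A	U	D	U	D	D	C	D	D	D	C	D	-	D	U	U	D
17	D	-	-	C	-	-	-	-	-	-	D	-	-	C	C	D	D	U	-	-	-	-	-	-
18	-	-	-	-	-	-	-	-	-	-	-	-	-	A	-	-	-	U	-	-	-	-	-	-
19	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	#	G	G	G	G	G
20	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G
21	G	A	A	D	D	D	D	C	D	D	D	D	D	C	D	D	G	D	D	D	D	D	C	D
22	G	A	G	G	G	A	G	G	G	G	G	A	A	G	G	G	G	G	A	A	G	G	A	U
23	A	A	A	C	U	G	C	G	A	A	A	G	G	A	A	A	A	G	G	G	A	A	C	A
24	G	G	G	G	A	G	A	A	A	A	G	G	G	G	G	G	G	G	G	G	G	A	G	A
25	C	U	C	C	U	C	C	C	C	C	C	C	C	C	C	C	C	U	C	C	C	C	C	C
26	R	R	A	R	A	A	U	A	A	A	R	R	R	G	A	A	R	A	R	R	A	A	G	A
27	C	C	C	P	C	P	C	C	C	C	P	C	C	G	P	P	P	C	A	A	C	C	G	P
28	U	U	C	P	C	C	C	C	C	A	G	U	C	C	P	C	P	U	C	A	C	C	C	C
29	U	U	G	C	C	G	G	G	A	G	C	G	A	G	U	G	A	U	A	G	U	G	A	U
30	G	G	G	G	G	G	G	C	G	C	C	G	G	G	G	G	G	G	G	A	C	G	G	G
31	C	A	C	G	C	A	A	G	C	G	G	A	A	G	A	P	A	C	A	A	C	A	A	C
32	U	C	C	C	C	C	B	C	C	P	C	P	C	C	C	C	B	U	hc	C	C	C	C	U
33	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U	U
34	I	I	{	Q	G	G	N	C	G	G	G	U	.	U	C	C	#	U	I	G	G	B	G	I
35	G	C	C	U	U	C	U	U	C	U	A	A	A	U	U	A	A	G	G	C	G	C	U	A
36	C	G	U	U	C	A	G	C	C	G	U	G	A	U	U	U	A	G	A	U	U	A	A	C
37	A	K	6	6	A	K	A	A	A	K	6	K	K	A	6	6	*	K	*	6	6	*	*	A
38	C	A	A	A	A	A	A	C	G	C	A	C	A	A	A	A	A	P	A	A	A	A	A	?
39	G	P	G	C	G	P	P	C	G	C	C	P	P	C	P	P	P	G	P	G	P	P	P	G
40	C	C	C	C	G	C	C	G	C	G	G	C	C	C	C	C	?	C	C	U	G	C	C	C
41	A	A	C	G	G	C	C	C	U	C	G	C	U	C	A	C	U	A	U	C	A	C	C	A
42	A	A	G	A	G	G	A	G	G	U	A	A	G	G	A	G	A	A	G	A	G	G	G	G
43	G	G	G	A	G	U	G	G	G	G	G	G	G	C	A	A	U	G	U	U	G	A	C	A
44	A	A	A	A	A	A	C	A	A	A	A	U	J	G	G	A	A	G	J	J	A	A	U	A
45	G	G	G	G	G	A	G	G	G	A	G	-	-	G	G	G	G	G	-	-	G	G	-	G
46	-	-	-	-	-	-	-	-	-	-	-	C	G	-	-	-	-	-	G	G	-	-	G	-
47	-	-	-	-	-	-	-	-	-	-	-	C	C	-	-	-	-	-	G	G	-	-	C	-
48	-	-	-	-	-	-	-	-	-	-	-	C	C	-	-	-	-	-	G	-	-	-	C	-
49	?	?	G	G	A	A	?	?	?	?	A	?	G	C	A	A	?	?	G	G	G	G	G	?
50	C	G	C	G	C	C	?	?	U	U	C	U	U	C	A	C	C	C	C	C	U	U	G	C
51	G	G	A	U	G	C	G	G	G	G	U	G	G	G	G	A	U	A	A	G	A	G	A	C
52	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	A	G	G	G	G	G	G	G	G
53	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G
54	T	T	T	.	T	U	U	T	T	U	T	T	T	U	T	T	T	T	T	T	T	T	T	T
55	P	P	P	P	P	P	P	P	P	P	P	P	P	U	P	P	P	P	P	P	P	P	P	P
56	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C
57	G	G	G	G	A	G	G	G	G	G	A	A	G	A	G	G	G	A	G	G	G	G	G	G
58	A	A	A	"	A	A	A	A	A	A	A	A	"	A	A	A	"	A	A	A	A	A	A	A
59	U	A	A	G	U	A	A	A	U	A	G	A	A	A	G	A	U	A	A	A	U	A	A	A
60	U	U	U	C	U	U	U	U	U	U	U	U	U	U	U	U	?	U	U	U	U	U	U	U
61	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C
62	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	U	C	C	C	C	C	C	C	C
63	C	C	U	A	C	G	C	C	C	C	A	C	C	C	C	C	G	U	U	C	U	U	G	G
64	G	U	G	C	G	G	G	G	G	A	C	A	A	G	U	U	G	G	G	G	A	G	U	G
65	G	G	G	C	U	U	G	G	G	G	U	C	C	G	C	U	G	G	C	G	C	C	C	G
66	C	C	C	C	C	U	U	U	C	U	A	U	U	C	A	A	U	C	C	C	A	C	C	C
67	G	G	G	A	C	G	G	G	C	A	A	G	U	G	U	G	C	U	G	U	G	G	C	G
68	G	G	G	G	G	U	G	G	C	A	G	C	C	G	C	C	U	G	C	U	U	C	C	G
69	C	G	G	G	U	G	G	G	C	C	G	U	U	G	A	C	C	G	C	U	C	C	C	A
70	U	C	G	G	G	G	A	G	C	G	C	G	G	C	G	G	G	C	U	G	G	C	U	A
71	C	U	G	A	U	C	C	G	G	G	C	G	A	C	U	G	G	C	C	U	G	C	C	C
72	C	C	U	C	C	C	C	A	C	?	C	C	C	C	C	C	C	G	C	C	C	U	C	C
73	A	G	A	G	G	U	U	A	A	A	A	A	A	G	A	A	A	A	G	G	A	G	A	A
74	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C
75	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C
76	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A
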