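class	position	codes	sign	note
Ala	3	G	attract	
Ala	17	D	attract	
Ala	35	G	attract	
Ala	36	C	attract	
Ala	70	U	attract	
Ala	71	C	attract	
Arg	21	A	attract	
Arg	35	C	attract	
Arg	36	G	attract	
Arg2	21	A	attract	
Arg2	35	C	attract	
Arg2	36	U	attract	
Arg2	69	G	attract	
Arg2	72	U	attract	
Asn	5	C	attract	
Asn	14	U	attract	
Asn	35	U	attract	
Asn	37	6	attract	
Asn	39	C	attract	
Asn	41	G	attract	
Asn	63	C	repel	
Asn	73	A	repel	
Asp	34	G,8,Q	attract	degenerate wobble cell
Asp	35	U	attract	
Asp	36	C	attract	
Asp	73	G	attract	
Cys	9	G	attract	
Cys	34	G	attract	
Cys	35	C	attract	
Cys	36	A	attract	
Cys	63	G	attract	
Cys	73	U	attract	
Gln	1	G	repel	
Gln	35	U	attract	
Gln	36	G	attract	
Gln	41	C	attract	
Gln	44	A	repel	
Gln	58	A	repel	
Gln	70	A	attract	
Gln	71	C	attract	
Glu	12	C	attract	
Glu	16	A	attract	
Glu	24	A	attract	
Glu	35	U	attract	
Glu	36	C	attract	
Glu	39	C	attract	
Glu	50	A	attract	
Gly	35	C	attract	
Gly	36	C	attract	
His	-1	G	attract	
His	2	C	attract	
His	17	U	attract	
His	35	U	attract	
His	36	G	attract	
His	37	G	attract	
Ile	2	G	attract	
Ile	7	G	repel	
Ile	35	A	attract	
Ile	36	U	attract	
Ile	37	6	attract	
Ile	40	G	attract	
Ile	41	G	attract	
Ile	70	G	repel	
Leu	35	A	attract	
Leu	36	G	attract	
Leu	48	-	repel	
Leu	55	G	attract	
Leu2	12	A	attract	
Leu2	13	C	repel	
Leu2	35	A	attract	
Leu2	36	A	attract	
Leu2	48	-	repel	
LysI	4	C	attract	
LysI	18	-	repel	
LysI	28	C	attract	
LysI	35	U	attract	
LysI	36	U	attract	
LysI	43	G	repel	
LysI	71	C	attract	
LysII	7	G	repel	
LysII	29	U	attract	
LysII	34	G	repel	printed ')~G'; leading ')' typographically ambiguous
LysII	35	U	attract	
LysII	36	U	attract	
LysII	67	G	repel	
Met	7	G	attract	
Met	11	G	attract	
Met	31	P	attract	
Met	34	M,C,B	attract	degenerate wobble cell
Met	35	A	attract	
Met	36	U	attract	
Phe	21	G	attract	
Phe	23	A	attract	
Phe	34	G,#	attract	degenerate wobble cell
Phe	35	A	attract	
Phe	36	A	attract	
Phe	44	G	attract	
Pro	35	G	attract	
Pro	36	G	attract	
Pro	37	K	attract	
Ser	25	A	attract	
Ser	35	G	attract	
Ser	36	A	attract	
Ser	48	-	repel	
Ser	73	G	attract	
Ser2	20	-	attract	
Ser2	34	7,G	attract	printed '34 7G'; degenerate wobble cell
Ser2	35	C	attract	
Ser2	36	U	attract	
Ser2	46	-	repel	
Thr	2	C	attract	
Thr	35	G	attract	
Thr	36	U	attract	
Thr	73	U	attract	
Trp	22	G	attract	
Trp	34	B	attract	
Trp	35	C	attract	
Trp	36	A	attract	
Trp	70	C	attract	
Trp	72	U	attract	
Trp	73	U	repel	
Tyr	21	C	attract	
Tyr	34	G	attract	
Tyr	35	U	attract	
Tyr	36	A	attract	
Tyr	45	-	attract	
Tyr	63	C	repel	
Val	35	A	attract	
Val	36	C	attract	
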