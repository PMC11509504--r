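class	amino_acid	tandem35	tandem36	remark	molecular_weight
Ala	Alanine	G	C	2-letter gen. code	89.09
Arg	Arginine	C	G	degenerate pos. 36	174.2
Arg2	Arginine	C	U	degenerate pos. 36	174.2
Asn	Asparagine	U	U	3-letter gen. code	132.12
Asp	Aspartic acid	U	C	3-letter gen. code	133.1
Cys	Cysteine	C	A	3-letter gen. code	121.16
Gln	Glutamine	U	G	3-letter gen. code	146.15
Glu	Glutamic acid	U	C	3-letter gen. code	147.13
Gly	Glycine	C	C	2-letter gen. code	75.07
His	Histidine	U	G	3-letter gen. code	155.15
Ile	Isoleucine	A	U	3-letter gen. code	131.17
Leu	Leucine	A	G	degenerate pos. 36	131.17
Leu2	Leucine	A	A	degenerate pos. 36	131.17
LysI	Lysine	U	U	synthetase class I	146.19
LysII	Lysine	U	U	synthetase class II	146.19
Met	Methionine	A	U	3-letter gen. code	149.21
Phe	Phenylalanine	A	A	3-letter gen. code	165.19
Pro	Proline	G	G	2-letter gen. code	115.13
Ser	Serine	G	A	deg. pos. 35 36	105.09
Ser2	Serine	C	U	deg. pos. 35 36	105.09
Thr	Threonine	G	U	2-letter gen. code	119.12
Trp	Tryptophan	C	A	3-letter gen. code	204.23
Tyr	Tyrosine	U	A	3-letter gen. code	181.19
Val	Valine	A	C	2-letter gen. code	117.15
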