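code	name	parent_base
A	adenosine	A
U	uridine	U
G	guanosine	G
C	cytidine	C
D	dihydrouridine	U
P	pseudouridine	U
T	5-methyluridine	U
K	1-methylguanosine	G
L	N2-methylguanosine	G
R	N2,N2-dimethylguanosine	G
M	N4-acetylcytidine	C
B	2'-O-methylcytidine	C
Q	queuosine	G
N	modified uridine (wobble)	U
I	inosine	A
J	2'-O-methyluridine	U
#	2'-O-methylguanosine	G
6	N6-threonylcarbamoyladenosine	A
7	7-methylguanosine	G
8	modified queuosine	G
*	modified adenosine (pos. 37)	A
"	1-methyladenosine	A
?	5-methylcytidine	C
.	unassigned modified nucleoside	none
{	unassigned modified nucleoside	none
(	unassigned modified nucleoside	none
)	unassigned modified nucleoside	none
hc	unassigned modified nucleoside	none
-	empty position	none
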