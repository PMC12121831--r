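# aminocode-v1
A	A
B	WA
C	C
D	D
E	E
F	F
G	G
H	H
I	I
J	WC
K	K
L	L
M	M
N	N
O	WD
P	P
Q	Q
R	R
S	S
T	T
U	WE
V	V
W	WW
X	WF
Y	Y
Z	WG
0	WH
1	WI
2	WK
3	WL
4	WM
5	WN
6	WP
7	WQ
8	WR
9	WS
<SPACE>	WT
.	WVA
,	WVC
;	WVD
:	WVE
!	WVF
?	WVG
-	WVH
'	WVI
"	WVK
(	WVL
)	WVM
/	WVN
&	WVP
%	WVQ
+	WVR
=	WVS
*	WVT
[	WVV
]	WVW
_	WVY
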