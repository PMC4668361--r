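# id: IGHV2-consensus-synthetic
# chain_class: heavy
# subgroup: VH2
kabat_number	insertion	aa	region
1		Q	FR1
2		V	FR1
3		T	FR1
4		L	FR1
5		K	FR1
6		E	FR1
7		S	FR1
8		G	FR1
9		P	FR1
10		V	FR1
11		L	FR1
12		V	FR1
13		K	FR1
14		P	FR1
15		T	FR1
16		E	FR1
17		T	FR1
18		L	FR1
19		T	FR1
20		L	FR1
21		T	FR1
22		C	FR1
23		T	FR1
24		V	FR1
25		S	FR1
26		G	FR1
27		F	FR1
28		S	FR1
29		L	FR1
30		S	FR1
31		N	CDR1
32		A	CDR1
33		R	CDR1
34		M	CDR1
35		G	CDR1
36		W	FR2
37		I	FR2
38		R	FR2
39		Q	FR2
40		P	FR2
41		P	FR2
42		G	FR2
43		K	FR2
44		A	FR2
45		L	FR2
46		E	FR2
47		W	FR2
48		L	FR2
49		A	FR2
50		R	CDR2
51		I	CDR2
52		D	CDR2
53		W	CDR2
54		D	CDR2
55		D	CDR2
56		D	CDR2
57		K	CDR2
58		F	CDR2
59		Y	CDR2
60		S	CDR2
61		T	CDR2
62		S	CDR2
63		L	CDR2
64		K	CDR2
65		T	CDR2
66		R	FR3
67		L	FR3
68		T	FR3
69		I	FR3
70		S	FR3
71		K	FR3
72		D	FR3
73		T	FR3
74		S	FR3
75		K	FR3
76		N	FR3
77		Q	FR3
78		V	FR3
79		V	FR3
80		L	FR3
81		T	FR3
82		M	FR3
83		T	FR3
84		N	FR3
85		M	FR3
86		D	FR3
87		P	FR3
88		V	FR3
89		D	FR3
90		T	FR3
91		A	FR3
92		Y	FR3
93		Y	FR3
94		C	FR3
95		A	CDR3
96		R	CDR3
97		I	CDR3
98		R	CDR3
99		V	CDR3
100		G	CDR3
101		A	CDR3
102		Y	CDR3
103		W	FR4
104		G	FR4
105		Q	FR4
106		G	FR4
107		T	FR4
108		L	FR4
109		V	FR4
110		T	FR4
111		V	FR4
112		S	FR4
113		S	FR4
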