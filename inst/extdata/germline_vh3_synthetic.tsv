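# id: IGHV3-consensus-synthetic
# chain_class: heavy
# subgroup: VH3
kabat_number	insertion	aa	region
1		E	FR1
2		V	FR1
3		Q	FR1
4		L	FR1
5		V	FR1
6		E	FR1
7		S	FR1
8		G	FR1
9		G	FR1
10		G	FR1
11		L	FR1
12		V	FR1
13		Q	FR1
14		P	FR1
15		G	FR1
16		G	FR1
17		S	FR1
18		L	FR1
19		R	FR1
20		L	FR1
21		S	FR1
22		C	FR1
23		A	FR1
24		A	FR1
25		S	FR1
26		G	FR1
27		F	FR1
28		T	FR1
29		F	FR1
30		S	FR1
31		S	CDR1
32		Y	CDR1
33		A	CDR1
34		M	CDR1
35		S	CDR1
36		W	FR2
37		V	FR2
38		R	FR2
39		Q	FR2
40		A	FR2
41		P	FR2
42		G	FR2
43		K	FR2
44		G	FR2
45		L	FR2
46		E	FR2
47		W	FR2
48		V	FR2
49		S	FR2
50		V	CDR2
51		I	CDR2
52		S	CDR2
53		G	CDR2
54		S	CDR2
55		G	CDR2
56		G	CDR2
57		S	CDR2
58		T	CDR2
59		Y	CDR2
60		A	CDR2
61		D	CDR2
62		S	CDR2
63		V	CDR2
64		K	CDR2
65		G	CDR2
66		R	FR3
67		F	FR3
68		T	FR3
69		I	FR3
70		S	FR3
71		R	FR3
72		D	FR3
73		N	FR3
74		S	FR3
75		K	FR3
76		N	FR3
77		T	FR3
78		L	FR3
79		Y	FR3
80		L	FR3
81		Q	FR3
82		M	FR3
83		N	FR3
84		S	FR3
85		L	FR3
86		R	FR3
87		A	FR3
88		E	FR3
89		D	FR3
90		T	FR3
91		A	FR3
92		Y	FR3
93		Y	FR3
94		C	FR3
95		A	CDR3
96		K	CDR3
97		G	CDR3
98		Y	CDR3
99		S	CDR3
100		F	CDR3
101		D	CDR3
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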