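# id: IGKV1-consensus-synthetic
# chain_class: kappa
# subgroup: kappa1
kabat_number	insertion	aa	region
1		D	FR1
2		I	FR1
3		Q	FR1
4		M	FR1
5		T	FR1
6		Q	FR1
7		S	FR1
8		P	FR1
9		S	FR1
10		S	FR1
11		L	FR1
12		S	FR1
13		A	FR1
14		S	FR1
15		V	FR1
16		G	FR1
17		D	FR1
18		R	FR1
19		V	FR1
20		T	FR1
21		I	FR1
22		T	FR1
23		C	FR1
24		R	CDR1
25		A	CDR1
26		S	CDR1
27		Q	CDR1
28		S	CDR1
29		I	CDR1
30		S	CDR1
31		S	CDR1
32		Y	CDR1
33		L	CDR1
34		N	CDR1
35		W	FR2
36		Y	FR2
37		Q	FR2
38		Q	FR2
39		K	FR2
40		P	FR2
41		G	FR2
42		K	FR2
43		A	FR2
44		P	FR2
45		K	FR2
46		L	FR2
47		L	FR2
48		I	FR2
49		Y	FR2
50		A	CDR2
51		A	CDR2
52		S	CDR2
53		S	CDR2
54		L	CDR2
55		Q	CDR2
56		S	CDR2
57		G	FR3
58		V	FR3
59		P	FR3
60		S	FR3
61		R	FR3
62		F	FR3
63		S	FR3
64		G	FR3
65		S	FR3
66		G	FR3
67		S	FR3
68		G	FR3
69		T	FR3
70		D	FR3
71		F	FR3
72		T	FR3
73		L	FR3
74		T	FR3
75		I	FR3
76		S	FR3
77		S	FR3
78		L	FR3
79		Q	FR3
80		P	FR3
81		E	FR3
82		D	FR3
83		F	FR3
84		A	FR3
85		T	FR3
86		Y	FR3
87		Y	FR3
88		C	FR3
89		Q	CDR3
90		Q	CDR3
91		S	CDR3
92		Y	CDR3
93		S	CDR3
94		T	CDR3
95		P	CDR3
96		L	CDR3
97		T	CDR3
98		F	FR4
99		G	FR4
100		Q	FR4
101		G	FR4
102		T	FR4
103		K	FR4
104		V	FR4
105		E	FR4
106		I	FR4
107		K	FR4
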