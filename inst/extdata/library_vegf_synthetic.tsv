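chain	kabat_position	from_aa	to_aa	support	name	filters_passed
light	1	D	M	5	D1M	framework;buried;not_excluded;supported
light	2	I	E	8	I2E	framework;buried;not_excluded;supported
light	3	Q	L	2	Q3L	framework;buried;not_excluded;supported
light	4	M	H	11	M4H	framework;buried;not_excluded;supported
light	5	T	V	8	T5V	framework;buried;not_excluded;supported
light	7	S	W	3	S7W	framework;buried;not_excluded;supported
light	8	P	N	2	P8N	framework;buried;not_excluded;supported
light	9	S	V	6	S9V	framework;buried;not_excluded;supported
light	11	L	N	5	L11N	framework;buried;not_excluded;supported
light	12	S	E	12	S12E	framework;buried;not_excluded;supported
light	15	V	G	11	V15G	framework;buried;not_excluded;supported
light	17	D	G	4	D17G	framework;buried;not_excluded;supported
light	22	T	K	12	T22K	framework;buried;not_excluded;supported
light	23	C	R	4	C23R	framework;buried;not_excluded;supported
light	35	W	L	10	W35L	framework;buried;not_excluded;supported
light	36	Y	N	2	Y36N	framework;buried;not_excluded;supported
light	38	Q	A	5	Q38A	framework;buried;not_excluded;supported
light	39	K	N	8	K39N	framework;buried;not_excluded;supported
light	42	K	H	7	K42H	framework;buried;not_excluded;supported
light	45	K	H	9	K45H	framework;buried;not_excluded;supported
light	47	L	W	6	L47W	framework;buried;not_excluded;supported
light	48	I	M	8	I48M	framework;buried;not_excluded;supported
light	49	Y	L	1	Y49L	framework;buried;not_excluded;supported
light	57	G	K	9	G57K	framework;buried;not_excluded;supported
light	58	V	Y	4	V58Y	framework;buried;not_excluded;supported
light	59	P	T	5	P59T	framework;buried;not_excluded;supported
light	60	S	T	3	S60T	framework;buried;not_excluded;supported
light	61	R	K	3	R61K	framework;buried;not_excluded;supported
light	62	F	T	4	F62T	framework;buried;not_excluded;supported
light	64	G	S	4	G64S	framework;buried;not_excluded;supported
light	66	G	W	8	G66W	framework;buried;not_excluded;supported
light	68	G	I	10	G68I	framework;buried;not_excluded;supported
light	69	T	C	9	T69C	framework;buried;not_excluded;supported
light	73	L	D	2	L73D	framework;buried;not_excluded;supported
light	76	S	Q	10	S76Q	framework;buried;not_excluded;supported
light	77	S	Y	10	S77Y	framework;buried;not_excluded;supported
light	78	L	M	2	L78M	framework;buried;not_excluded;supported
light	80	P	F	5	P80F	framework;buried;not_excluded;supported
light	82	D	A	4	D82A	framework;buried;not_excluded;supported
light	84	A	F	11	A84F	framework;buried;not_excluded;supported
light	86	Y	Q	12	Y86Q	framework;buried;not_excluded;supported
light	87	Y	E	10	Y87E	framework;buried;not_excluded;supported
light	88	C	W	2	C88W	framework;buried;not_excluded;supported
light	99	G	E	2	G99E	framework;buried;not_excluded;supported
light	102	T	M	4	T102M	framework;buried;not_excluded;supported
light	103	K	C	4	K103C	framework;buried;not_excluded;supported
light	106	I	R	12	I106R	framework;buried;not_excluded;supported
heavy	6	E	Q	9	E6Q	framework;buried;not_excluded;supported
heavy	14	P	C	1	P14C	framework;buried;not_excluded;supported
heavy	15	G	D	8	G15D	framework;buried;not_excluded;supported
heavy	16	G	C	8	G16C	framework;buried;not_excluded;supported
heavy	20	L	D	5	L20D	framework;buried;not_excluded;supported
heavy	21	S	I	2	S21I	framework;buried;not_excluded;supported
heavy	22	C	F	4	C22F	framework;buried;not_excluded;supported
heavy	24	A	M	8	A24M	framework;buried;not_excluded;supported
heavy	27	F	E	4	F27E	framework;buried;not_excluded;supported
heavy	28	T	W	10	T28W	framework;buried;not_excluded;supported
heavy	37	V	I	2	V37I	framework;buried;not_excluded;supported
heavy	37	V	G	5	V37G	framework;buried;not_excluded;supported
heavy	38	R	Q	3	R38Q	framework;buried;not_excluded;supported
heavy	43	K	Q	9	K43Q	framework;buried;not_excluded;supported
heavy	44	G	E	4	G44E	framework;buried;not_excluded;supported
heavy	48	V	L	2	V48L	framework;buried;not_excluded;supported
heavy	48	V	I	4	V48I	framework;buried;not_excluded;supported
heavy	66	R	H	8	R66H	framework;buried;not_excluded;supported
heavy	67	F	N	5	F67N	framework;buried;not_excluded;supported
heavy	67	R	K	2	R67K	framework;buried;not_excluded;supported
heavy	70	S	K	4	S70K	framework;buried;not_excluded;supported
heavy	71	R	T	1	R71T	framework;buried;not_excluded;supported
heavy	72	D	V	6	D72V	framework;buried;not_excluded;supported
heavy	74	S	W	5	S74W	framework;buried;not_excluded;supported
heavy	77	T	W	1	T77W	framework;buried;not_excluded;supported
heavy	78	L	E	1	L78E	framework;buried;not_excluded;supported
heavy	79	Y	P	2	Y79P	framework;buried;not_excluded;supported
heavy	88	E	D	1	E88D	framework;buried;not_excluded;supported
heavy	89	D	H	3	D89H	framework;buried;not_excluded;supported
heavy	91	A	Y	2	A91Y	framework;buried;not_excluded;supported
heavy	92	Y	I	5	Y92I	framework;buried;not_excluded;supported
heavy	105	Q	I	7	Q105I	framework;buried;not_excluded;supported
heavy	106	G	I	7	G106I	framework;buried;not_excluded;supported
heavy	107	T	R	2	T107R	framework;buried;not_excluded;supported
heavy	108	L	W	4	L108W	framework;buried;not_excluded;supported
heavy	111	V	T	3	V111T	framework;buried;not_excluded;supported
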