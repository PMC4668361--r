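chain	kabat_position	from_aa	to_aa	support	name	filters_passed
light	4	M	L	8	M4L	framework;buried;not_excluded;supported
light	38	Q	R	3	Q38R	framework;buried;not_excluded;supported
light	79	Q	F	5	Q79F	framework;buried;not_excluded;supported
light	81	E	L	2	E81L	framework;buried;not_excluded;supported
light	99	G	C	9	G99C	framework;buried;not_excluded;supported
heavy	6	E	Q	1	E6Q	framework;buried;not_excluded;supported
heavy	8	G	A	9	G8A	framework;buried;not_excluded;supported
heavy	11	L	K	6	L11K	framework;buried;not_excluded;supported
heavy	19	T	E	10	T19E	framework;buried;not_excluded;supported
heavy	20	L	G	12	L20G	framework;buried;not_excluded;supported
heavy	24	V	D	8	V24D	framework;buried;not_excluded;supported
heavy	26	G	N	3	G26N	framework;buried;not_excluded;supported
heavy	27	F	L	10	F27L	framework;buried;not_excluded;supported
heavy	27	F	S	9	F27S	framework;buried;not_excluded;supported
heavy	36	W	N	9	W36N	framework;buried;not_excluded;supported
heavy	41	P	S	1	P41S	framework;buried;not_excluded;supported
heavy	42	G	V	3	G42V	framework;buried;not_excluded;supported
heavy	45	L	F	1	L45F	framework;buried;not_excluded;supported
heavy	46	E	R	9	E46R	framework;buried;not_excluded;supported
heavy	49	A	S	1	A49S	framework;buried;not_excluded;supported
heavy	67	L	N	9	L67N	framework;buried;not_excluded;supported
heavy	68	T	D	12	T68D	framework;buried;not_excluded;supported
heavy	73	T	Q	9	T73Q	framework;buried;not_excluded;supported
heavy	74	S	I	6	S74I	framework;buried;not_excluded;supported
heavy	75	K	Q	3	K75Q	framework;buried;not_excluded;supported
heavy	77	Q	H	6	Q77H	framework;buried;not_excluded;supported
heavy	78	V	L	12	V78L	framework;buried;not_excluded;supported
heavy	80	L	A	1	L80A	framework;buried;not_excluded;supported
heavy	81	T	R	11	T81R	framework;buried;not_excluded;supported
heavy	83	T	D	7	T83D	framework;buried;not_excluded;supported
heavy	87	P	N	10	P87N	framework;buried;not_excluded;supported
heavy	108	L	T	12	L108T	framework;buried;not_excluded;supported
heavy	112	S	Q	3	S112Q	framework;buried;not_excluded;supported
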