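population	haplogroup	count
DB	D4	8
DB	D4j3	2
DB	D5	3
DB	G2a	3
DB	G3	1
DB	C4d	2
DB	C	1
DB	Z	1
DB	M7b	2
DB	M9a	2
DB	M9b	1
DB	M10	2
DB	M13a1b	2
DB	A4	1
DB	A	2
DB	N9a	2
DB	B4	3
DB	B5b	2
DB	F1	4
DB	F1a	1
DB	R	1
DF	D4	4
DF	D4j3	2
DF	D5	2
DF	G2a	4
DF	G2b1b	1
DF	G3	2
DF	G3a1	1
DF	M9a	4
DF	M7b	1
DF	M10	1
DF	M13a1b	2
DF	Z	1
DF	A4	2
DF	A	2
DF	B4	2
DF	B5b	1
DF	F1	5
DF	N9a	2
DF	R	1
XL	D4	16
XL	D5	5
XL	G2a	6
XL	G2b1b	1
XL	G3	4
XL	C4d	1
XL	C	1
XL	Z	2
XL	M7b	4
XL	M9a	12
XL	M9a1a	2
XL	M9a1b1	2
XL	M9b	1
XL	M10	3
XL	M13a1b	4
XL	M74a	1
XL	C4a2'3'4	4
XL	A4	5
XL	A	6
XL	A11	2
XL	N9a	3
XL	B4	8
XL	B5b	3
XL	F1	10
XL	F1a	5
XL	R	8
YJ	D4	26
YJ	D5	6
YJ	D5a2a	3
YJ	G2a	5
YJ	G2b1b	9
YJ	G3	13
YJ	G3a1	2
YJ	C4d	12
YJ	C4a2'3'4	4
YJ	C	2
YJ	Z	3
YJ	M7b	5
YJ	M9a	13
YJ	M9a1a	2
YJ	M9a1b1	2
YJ	M10	2
YJ	M13a1b	1
YJ	M62b	3
YJ	A4	24
YJ	A	5
YJ	A11	1
YJ	A11b	2
YJ	N9a	2
YJ	B4	5
YJ	B5b	3
YJ	F1	3
YJ	F1a	4
YJ	U	2
YJ	R	28
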