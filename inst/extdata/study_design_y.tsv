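population	haplogroup	count
DB	D1	8
DB	O3a2c1a	4
DB	O3a2c1*	1
DB	C*	1
DB	O2a1	2
DB	J	1
DB	R2	1
DF	D1	2
DF	D3a	3
DF	O1a1	1
DF	O3a2c1a	2
DF	N1c1a	2
DF	O2a1	2
DF	O3*	2
DF	Q1a1	2
XL	D1	4
XL	D3a	6
XL	O3a1c	7
XL	O1a1	4
XL	O3a2c1a	5
XL	O3a2c1*	3
XL	N1c1a	1
XL	C*	1
XL	O2a1	5
XL	J	2
XL	R2	1
XL	O3*	4
XL	Q1a1	3
YJ	D1	3
YJ	C3	5
YJ	O1a1	10
YJ	O3a2c1a	9
YJ	O3a2c1*	3
YJ	D3a	8
YJ	O2a1	4
YJ	O3*	3
YJ	Q1a1	2
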