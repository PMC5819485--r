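source_code	target_class	percent
10	C+G	100
11	C+G	100
12	C+G	100
20	C+G	100
30	C+G	100
40	C+G	100
50	FOR	100
60	FOR	100
61	FOR	100
62	SAV	100
70	FOR	100
71	FOR	100
72	SAV	100
80	FOR	100
81	FOR	100
82	SAV	100
90	FOR	100
100	SAV	100
110	SAV	100
120	SHR	100
121	SHR	100
122	SHR	100
130	C+G	100
140	BSV	100
150	BSV	100
152	BSV	100
153	BSV	100
160	WET	100
170	WET	100
180	WET	100
190	URB	100
200	BSV	100
201	BSV	100
202	BSV	100
210	WAT	100
220	SNO	100
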