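class	base	body	stem	tip
base	392	4	14	2
body	15	290	13	33
stem	11	14	290	2
tip	1	3	0	295
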