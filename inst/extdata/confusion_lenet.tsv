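class	base	body	stem	tip
base	344	12	52	4
body	15	280	26	30
stem	14	29	270	4
tip	91	31	8	169
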