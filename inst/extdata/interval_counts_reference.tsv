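cup_class	A	G	U	C
unused	27	113	42	30
under	4	63	27	31
unbiased	45	26	113	117
over	132	6	26	30
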