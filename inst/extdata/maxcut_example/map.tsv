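gene	species
a1	a
b1	b
c1	c
d1	d
e1	e
f1	f
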