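name	operand_a	operand_b	set_a	set_b	type_name	type_a	type_b
bpb	bp	b	Si	Si	protein complex	peptide	peptide
2a	a	a	Si	Si	protein complex	peptide	peptide
ba	bpb	2a	Si	Si	protein complex	protein complex	protein complex
pol	o	ba	Si	Si	enzyme	peptide	protein complex
t.bp	g.bp	pol	G	Si	transcript	gene	enzyme
t.b	g.b	pol	G	Si	transcript	gene	enzyme
t.a	g.a	pol	G	Si	transcript	gene	enzyme
t.o	g.o	pol	G	Si	transcript	gene	enzyme
bp	t.bp	rib	Si	Se	peptide	transcript	ribosome
b	t.b	rib	Si	Se	peptide	transcript	ribosome
a	t.a	rib	Si	Se	peptide	transcript	ribosome
o	t.o	rib	Si	Se	peptide	transcript	ribosome
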