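name	operand_a	operand_b	set_a	set_b	type_name	type_a	type_b
a	b	c					
b	a	d					
f	e	h					
g	f	f					
i	a	b					
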