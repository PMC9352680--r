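term_class	position	base	value_kcal_mol	is_lower_limit
bound	1	A	0.00	0
bound	1	C	0.00	0
bound	1	U	0.00	0
bound	1	G	0.00	0
flip	3/4	A	0.00	0
flip	3/4	NN	0.00	0
extension	-2	C	0.00	0
coupling	5,8	A,U	0.00	0
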