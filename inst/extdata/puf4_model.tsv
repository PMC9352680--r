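term_class	position	base	value_kcal_mol	is_lower_limit
bound	1	A	3.69	0
bound	1	C	2.85	0
bound	1	U	0.00	0
bound	1	G	3.97	0
bound	2	A	2.50	0
bound	2	C	4.41	0
bound	2	U	4.39	0
bound	2	G	0.00	0
bound	3	A	2.67	0
bound	3	C	3.01	0
bound	3	U	0.00	0
bound	3	G	2.52	0
bound	4	A	0.00	0
bound	4	C	2.29	0
bound	4	U	1.75	0
bound	4	G	1.51	0
bound	5	A	0.89	0
bound	5	C	0.03	0
bound	5	U	0.00	0
bound	5	G	1.10	0
bound	6	A	0.00	0
bound	6	C	0.93	0
bound	6	U	0.85	0
bound	6	G	1.41	0
bound	7	A	2.48	0
bound	7	C	1.82	0
bound	7	U	0.00	0
bound	7	G	2.07	0
bound	8	A	0.00	0
bound	8	C	1.47	0
bound	8	U	1.33	0
bound	8	G	1.33	0
bound	9	A	0.60	0
bound	9	C	0.37	0
bound	9	U	0.00	0
bound	9	G	0.24	0
flip	3/4	A	1.63	0
flip	3/4	C	1.51	0
flip	3/4	U	1.60	0
flip	3/4	G	1.21	0
flip	3/4	NN	1.50	1
flip	4/5	A	2.00	1
flip	4/5	C	1.36	0
flip	4/5	U	1.75	0
flip	4/5	G	2.00	1
flip	4/5	NN	1.50	1
flip	5/6	A	2.00	1
flip	5/6	C	1.83	0
flip	5/6	U	1.68	0
flip	5/6	G	2.00	1
flip	5/6	NN	1.50	1
flip	6/7	A	-1.15	0
flip	6/7	C	-1.07	0
flip	6/7	U	-1.34	0
flip	6/7	G	-0.35	0
flip	6/7	NN	0.67	0
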