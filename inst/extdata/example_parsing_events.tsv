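onset_s	duration_s	trial_index	node	stimulus	phase	block_kind	block_200	rotated	transition_label	manipulated
0	1.25	0	d	4	parsing	walk	1	FALSE	n/a	FALSE
1.25	1.25	1	b	5	parsing	walk	1	FALSE	nonboundary	FALSE
2.5	1.25	2	d	4	parsing	walk	1	FALSE	nonboundary	FALSE
3.75	1.25	3	c	3	parsing	walk	1	FALSE	nonboundary	FALSE
5	1.25	4	b	5	parsing	walk	1	FALSE	nonboundary	FALSE
6.25	1.25	5	e	2	parsing	walk	1	FALSE	nonboundary	FALSE
7.5	1.25	6	c	3	parsing	walk	1	FALSE	nonboundary	FALSE
8.75	1.25	7	b	5	parsing	walk	1	FALSE	nonboundary	FALSE
10	1.25	8	c	3	parsing	walk	1	FALSE	nonboundary	FALSE
11.25	1.25	9	e	2	parsing	walk	1	FALSE	nonboundary	FALSE
12.5	1.25	10	f	8	parsing	walk	1	FALSE	novel_boundary	TRUE
13.75	1.25	11	g	7	parsing	walk	1	FALSE	nonboundary	FALSE
15	1.25	12	h	6	parsing	walk	1	FALSE	nonboundary	FALSE
16.25	1.25	13	f	8	parsing	walk	1	FALSE	nonboundary	FALSE
17.5	1.25	14	e	2	parsing	walk	1	FALSE	novel_boundary	TRUE
18.75	1.25	15	d	4	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
20	1.25	16	b	5	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
21.25	1.25	17	e	2	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
22.5	1.25	18	c	3	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
23.75	1.25	19	a	1	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
25	1.25	20	o	15	parsing	hamiltonian	1	FALSE	learned_boundary	FALSE
26.25	1.25	21	m	13	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
27.5	1.25	22	l	12	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
28.75	1.25	23	n	14	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
30	1.25	24	k	11	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
31.25	1.25	25	j	10	parsing	hamiltonian	1	FALSE	learned_boundary	FALSE
32.5	1.25	26	i	9	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
33.75	1.25	27	g	7	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
35	1.25	28	h	6	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
36.25	1.25	29	f	8	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
37.5	1.25	30	g	7	parsing	walk	1	FALSE	nonboundary	FALSE
38.75	1.25	31	h	6	parsing	walk	1	FALSE	nonboundary	FALSE
40	1.25	32	g	7	parsing	walk	1	FALSE	nonboundary	FALSE
41.25	1.25	33	h	6	parsing	walk	1	FALSE	nonboundary	FALSE
42.5	1.25	34	j	10	parsing	walk	1	FALSE	nonboundary	FALSE
43.75	1.25	35	i	9	parsing	walk	1	FALSE	nonboundary	FALSE
45	1.25	36	f	8	parsing	walk	1	FALSE	nonboundary	FALSE
46.25	1.25	37	e	2	parsing	walk	1	FALSE	novel_boundary	TRUE
47.5	1.25	38	d	4	parsing	walk	1	FALSE	nonboundary	FALSE
48.75	1.25	39	a	1	parsing	walk	1	FALSE	nonboundary	FALSE
50	1.25	40	b	5	parsing	walk	1	FALSE	nonboundary	FALSE
51.25	1.25	41	e	2	parsing	walk	1	FALSE	nonboundary	FALSE
52.5	1.25	42	c	3	parsing	walk	1	FALSE	nonboundary	FALSE
53.75	1.25	43	b	5	parsing	walk	1	FALSE	nonboundary	FALSE
55	1.25	44	a	1	parsing	walk	1	FALSE	nonboundary	FALSE
56.25	1.25	45	c	3	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
57.5	1.25	46	a	1	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
58.75	1.25	47	b	5	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
60	1.25	48	d	4	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
61.25	1.25	49	e	2	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
62.5	1.25	50	f	8	parsing	hamiltonian	1	FALSE	novel_boundary	TRUE
63.75	1.25	51	h	6	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
65	1.25	52	g	7	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
66.25	1.25	53	i	9	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
67.5	1.25	54	j	10	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
68.75	1.25	55	k	11	parsing	hamiltonian	1	FALSE	learned_boundary	FALSE
70	1.25	56	m	13	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
71.25	1.25	57	o	15	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
72.5	1.25	58	n	14	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
73.75	1.25	59	l	12	parsing	hamiltonian	1	FALSE	nonboundary	FALSE
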