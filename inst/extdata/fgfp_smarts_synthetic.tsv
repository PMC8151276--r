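# Functional-group substructure dialect for the 512-slot block of the
# concatenated fingerprint.  SYNTHETIC stand-in: the historical 512-slot
# functional-group fingerprint's pattern file is not redistributable here,
# so the package defines its own frozen dialect of named SMARTS patterns
# occupying the first slots of the block; remaining slots stay zero.
# Columns: slot (1-512), name, SMARTS.
1	alkane_carbon	[CX4]
2	alkene	[CX3]=[CX3]
3	alkyne	[CX2]#[CX2]
4	arene	c1ccccc1
5	aromatic_carbon	c
6	aromatic_nitrogen	n
7	aromatic_oxygen	o
8	aromatic_sulfur	s
9	primary_carbon	[CX4H3][#6]
10	secondary_carbon	[CX4H2]([#6])[#6]
11	tertiary_carbon	[CX4H1]([#6])([#6])[#6]
12	quaternary_carbon	[CX4]([#6])([#6])([#6])[#6]
13	alcohol	[OX2H][CX4]
14	primary_alcohol	[OX2H][CX4H2]
15	secondary_alcohol	[OX2H][CX4H1]
16	tertiary_alcohol	[OX2H][CX4D4]
17	phenol	[OX2H][c]
18	enol	[OX2H][CX3]=[CX3]
19	ether	[OD2]([#6])[#6]
20	dialkyl_ether	[OD2]([CX4])[CX4]
21	alkyl_aryl_ether	[OD2]([CX4])[c]
22	diaryl_ether	[OD2]([c])[c]
23	aldehyde	[CX3H1](=O)[#6]
24	ketone	[#6][CX3](=O)[#6]
25	carboxylic_acid	[CX3](=O)[OX2H1]
26	carboxylate	[CX3](=O)[O-]
27	ester	[CX3](=O)[OX2H0][#6]
28	lactone	[CX3R](=O)[OX2R][#6R]
29	carbonate	[OX2][CX3](=O)[OX2]
30	anhydride	[CX3](=O)[OX2][CX3](=O)
31	amide	[CX3](=O)[NX3]
32	primary_amide	[CX3](=O)[NX3H2]
33	secondary_amide	[CX3](=O)[NX3H1][#6]
34	tertiary_amide	[CX3](=O)[NX3H0]([#6])[#6]
35	lactam	[CX3R](=O)[NX3R]
36	carbamate	[NX3][CX3](=O)[OX2]
37	urea	[NX3][CX3](=O)[NX3]
38	guanidine	[NX3][CX3](=[NX2,NX3+])[NX3]
39	amidine	[NX3][CX3]=[NX2]
40	primary_amine	[NX3H2][CX4]
41	secondary_amine	[NX3H1]([CX4])[CX4]
42	tertiary_amine	[NX3H0]([CX4])([CX4])[CX4]
43	aryl_amine	[NX3][c]
44	quaternary_ammonium	[NX4+]
45	hydroxylamine	[NX3][OX2H]
46	nitrile	[NX1]#[CX2]
47	isonitrile	[CX1-]#[NX2+]
48	nitro	[$([NX3](=O)=O),$([NX3+](=O)[O-])]
49	nitroso	[NX2]=[OX1]
50	azo	[NX2]=[NX2]
51	azide	[NX2]=[NX2+]=[NX1-]
52	diazo	[CX3]=[NX2+]=[NX1-]
53	hydrazine	[NX3][NX3]
54	hydrazone	[NX3][NX2]=[CX3]
55	imine	[CX3]=[NX2][#6,#1]
56	oxime	[CX3]=[NX2][OX2H]
57	thiol	[SX2H]
58	thioether	[SX2H0]([#6])[#6]
59	disulfide	[SX2][SX2]
60	sulfoxide	[SX3](=[OX1])([#6])[#6]
61	sulfone	[SX4](=[OX1])(=[OX1])([#6])[#6]
62	sulfonamide	[SX4](=[OX1])(=[OX1])[NX3]
63	sulfonic_acid	[SX4](=[OX1])(=[OX1])[OX2H]
64	sulfonate_ester	[SX4](=[OX1])(=[OX1])[OX2H0][#6]
65	thiocarbonyl	[CX3]=[SX1]
66	thioamide	[CX3](=[SX1])[NX3]
67	thiourea	[NX3][CX3](=[SX1])[NX3]
68	isothiocyanate	[NX2]=[CX2]=[SX1]
69	fluoro	[F][#6]
70	chloro	[Cl][#6]
71	bromo	[Br][#6]
72	iodo	[I][#6]
73	trifluoromethyl	[CX4]([F])([F])[F]
74	difluoromethoxy	[OX2][CX4H1]([F])[F]
75	aryl_halide	[F,Cl,Br,I][c]
76	alkyl_halide	[F,Cl,Br,I][CX4]
77	acyl_halide	[CX3](=[OX1])[F,Cl,Br,I]
78	phosphate	[PX4](=[OX1])([OX2])([OX2])[OX2]
79	phosphonate	[PX4](=[OX1])([OX2])[#6]
80	phosphine	[PX3]
81	boronic_acid	[BX3]([OX2])[OX2]
82	pyridine	c1ccncc1
83	pyrimidine	c1ccncn1
84	pyrazine	c1cnccn1
85	pyridazine	c1ccnnc1
86	triazine	c1ncncn1
87	pyrrole	c1cc[nH]c1
88	furan	c1ccoc1
89	thiophene	c1ccsc1
90	imidazole	c1cnc[nH]1
91	pyrazole	c1cc[nH]n1
92	oxazole	c1cnco1
93	isoxazole	c1cnoc1
94	thiazole	c1cncs1
95	triazole	c1nc[nH]n1
96	tetrazole	c1nnn[nH]1
97	indole	c1ccc2[nH]ccc2c1
98	benzimidazole	c1ccc2[nH]cnc2c1
99	benzofuran	c1ccc2occc2c1
100	benzothiophene	c1ccc2sccc2c1
101	benzothiazole	c1ccc2scnc2c1
102	quinoline	c1ccc2ncccc2c1
103	isoquinoline	c1ccc2cnccc2c1
104	quinazoline	c1ccc2ncncc2c1
105	purine	c1nc2[nH]cnc2cn1
106	naphthalene	c1ccc2ccccc2c1
107	coumarin	O=c1ccc2ccccc2o1
108	xanthine_core	O=c1[nH]c(=O)c2[nH]cnc2[nH]1
109	piperidine	C1CCNCC1
110	piperazine	C1CNCCN1
111	morpholine	C1COCCN1
112	pyrrolidine	C1CCNC1
113	tetrahydrofuran	C1CCOC1
114	azetidine	C1CNC1
115	epoxide	C1OC1
116	aziridine	C1NC1
117	cyclopropane	C1CC1
118	cyclohexane	C1CCCCC1
119	spiro_carbon	[CX4](@[#6])(@[#6])(@[#6])@[#6]
120	methoxy	[OX2H0][CX4H3]
121	ethoxy	[OX2H0][CX4H2][CX4H3]
122	dimethylamino	[NX3]([CX4H3])[CX4H3]
123	acetyl	[CX3](=O)[CX4H3]
124	benzoyl	[CX3](=O)c1ccccc1
125	benzylamine_n	[NX3][CX4H2][c]
126	aminomethyl	[NX3][CX4H2]
127	hydroxymethyl	[OX2H][CX4H2]
128	carboxymethyl	[CX4H2][CX3](=O)[OX2H1]
129	n_methyl	[NX3][CX4H3]
130	halogen_any	[F,Cl,Br,I]
131	heteroatom_chain	[#7,#8,#16][CX4][#7,#8,#16]
132	conjugated_carbonyl	[CX3]=[CX3][CX3]=[OX1]
133	vinyl	[CX3H2]=[CX3H1]
134	allyl	[CX3H2]=[CX3H1][CX4H2]
135	gem_dimethyl	[CX4]([CX4H3])([CX4H3])
136	ortho_disub_arene	c1ccc(*)c(*)c1
137	para_disub_arene	*c1ccc(*)cc1
138	biphenyl	c1ccc(-c2ccccc2)cc1
139	diarylmethane	[c][CX4H2][c]
140	aryl_sulfonyl	[SX4](=[OX1])(=[OX1])[c]
141	aryl_carbonyl	[CX3](=[OX1])[c]
142	amino_acid_backbone	[NX3][CX4H1][CX3](=[OX1])[OX2H1]
143	peg_unit	[OX2][CX4H2][CX4H2][OX2]
144	nitrogen_any	[#7]
145	oxygen_any	[#8]
146	sulfur_any	[#16]
147	basic_nitrogen	[$([NX3H2,NX3H1,NX3H0;!$(N[C,S]=[O,S,N]);!$(N[a])])]
148	hbond_donor	[#7H,#8H]
149	hbond_acceptor	[$([#7;!$([nX3]);!$([NX3][C,S]=[O,S,N])]),$([#8;!$([OX2H0][C,S]=[O,S,N])])]
150	fused_bicyclic_aromatic	[cR2][cR2]
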