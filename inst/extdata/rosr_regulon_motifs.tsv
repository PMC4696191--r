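gene_id	product	cog_class	log2fc	motif	identity_pct	distance_nt
Rt617_78	Amino acid ABC transporter substrate-binding protein	E	5.097	TGAAATCCATATCGACACTTCT	72.2	0
Rt620_77	Urea ABC transporter ATP-binding protein	E	3.502	CGGCTTCAAGGCGCTGAATTCG	66.7	61
Rt619_162	ABC-type dipeptide/oligopeptide transport system, permease	EP	-4.011	CAGAATCCGGCGGTGC-TTCCG	68.2	-153
Rt619_164	Peptide ABC transporter ATPase	EP	-4.438	CGCATTCTTCTCCTCTATATCG	66.7	-281
Rt648_25	LacI family transcriptional regulator	G	3.147	CGGCGGATAATCCTTGATCTCG	66.7	-176
Rt794_16	ABC transporter ATP-binding protein	G	2.968	GCGCTTCGTGGCGTGGATTTCG	66.7	56
Rt794_99	Sugar ABC transporter	G	2.053	CGGATTCCAGTAGGGATTTTCG	72.2	85
Rt643_15	Sugar ABC transporter substrate-binding protein	G	-3.744	CGGGGTCAGCAACTGCATTTCG	72.2	-83
Rt620_14	Glycerol 3-phosphate ABC transporter	G	2.133	CGAAATTTCTCTAAATATTTCC	66.7	-174
Rt657_260	Cell division protein FtsK	D	-3.211	CGGCGTCGAGATCTCGACATCG	66.7	-216
Rt634_26	Flagellar biosynthesis repressor FlbT	N	-3.247	CGCAAGGTCGCGCTGGAATTCC	66.7	74
Rt634_27	Flagellar basal body rod modification protein FlgD	N	-3.391	CAGAAGGCAACGCTGAATTACG	66.7	65
Rt634_13	Flagellin B	N	-4.601	TCCGATCTCGATTTAGCTTTCT	66.7	-170
Rt634_5	Flagellar basal body P-ring biosynthesis protein FlgA	N	-3.438	GGAAATCACCGAGCTGATCTCG	59.1	-99
Rt628_11	Flagellar motor switch protein FliN	NU	-4.579	CCGGCTGCGGGCATGGATTTCG	66.7	-13
Rt761_94	Methyl-accepting chemotaxis protein	NT	-3.966	CGCAAACGCAGTGTGTATTTGA	54.5	-124
Rt628_20	Chemotaxis protein CheD	NT	-2.353	CGAATTGGAAGATTGGCTGTCG	66.7	145
Rt792_47	Chemotaxis protein	NT	-2.587	CGGAATGCAGCTATCCATTCCC	66.7	-36
Rt647_8	Chemotaxis protein	NT	-3.651	TAAATTCTACGCCAAGATCGCC	66.7	127
Rt628_24	Chemotaxis protein CheW	NT	-3.050	CGGAGTCCAGCCCGGATTTCG	72.7	98
Rt628_25	Chemotaxis protein CheA	NT	-2.793	CGGAGTCCAGCCCCGGATTTCG	72.7	98
Rt792_70	Chemotaxis protein	NT	-3.025	CGGATGACATCAGAGGATTTCG	72.2	-298
Rt628_22	Chemotaxis protein CheB	NT	-3.030	CGGCGTCTATGAATGGGTGGAG	66.7	-40
Rt620_4	Glycosyl transferase	M	5.444	CGAATACCAAAGCCTGATTTCG	66.7	-76
Rt620_5	Polysaccharide biosynthesis protein	M	5.090	CTGGCGCGACTGCTCGATTTCG	66.7	59
Rt794_35	Polysaccharide biosynthesis protein	M	2.433	CGGCATCGGCCGGTAGATGACG	66.7	-191
Rt768_57	Peptidoglycan hydrolase	M	-2.657	CCGCATCGGCACGATGATTTCG	66.7	-243
Rt679_3	Glycosyl transferase	M	-3.806	CCGATTCACTATCTCGATCTCG	66.7	-137
Rt621_6	UDP-N-acetylmuramoyl-L-alanyl-D-glutamate synthetase	M	-2.028	CGAAATCCGCTGCGAGATATAA	66.7	130
Rt623_92	Glycosyl transferase	M	-2.450	TGAAGTCTTGGGACTGACATCA	66.7	-106
Rt780_45	Polysaccharide biosynthesis protein	M	7.890	TTGAAACGA-GCCTGGATTACG	63.6	291
Rt627_76	Polysaccharide biosynthesis protein GelA	M	2.218	CGGATCGAAGCG-TG-AATTCG	63.6	22
Rt620_62	Exopolysaccharide biosynthesis protein PssA	M	-1.170	CGAAATGCTGTTGTTTAGTTCC	54.5	11
Rt772_12	Glycosyl transferase PssC	M	-1.451	CTGAAGCTCCGGGGCGAAGCTCG	63.6	-125
Rt780_150	Signal peptide protein	H	3.925	ATGCATCAAATACTGCATGTCG	66.7	-239
Rt622_32	Ubiquinol oxidase subunit II	C	-6.942	CGAAAAATCCTTCTTGATTTCA	66.7	-231
Rt620_122	Iron transporter	P	-2.510	CGGAAGGCAGCGATGGTGTTCT	66.7	73
Rt772_17	PrsD component of type I secretion system	MU	2.252	CTGCAGCTACGGGTCCATCAAG	59.1	-50
Rt646_16	Acyl-homoserine-lactone synthase (RaiI)	T	6.049	AGCAATCTATGAATGGAATCGT	66.7	64
Rt628_39	Histidine kinase (PhoR)	T	3.583	GGTAATCTAGCACCGTAATTTG	66.7	-200
Rt620_2	Crp/Fnr family transcriptional regulator	T	7.049	TTTCAACTAAATGTAGACTTGA	66.7	-129
Rt628_38	Chemotaxis protein CheY	T	4.010	GAGGATCTCGCCGGGGATTTCC	66.7	-299
Rt628_26	Chemotaxis protein CheY	T	-3.129	CGGAACCAATGTCAGCATTGAG	66.7	81
Rt648_50	PhoB family transcriptional regulator	TK	3.900	GGTCGTCAAGGTGTTGAACCAG	50.0	-167
Rt783_97	Transcriptional regulator	K	4.442	CGGTGTCGGCCATCGGCTTTCG	66.7	-224
Rt794_73	TetR family transcriptional regulator	K	3.385	CGTCATCTCGATGACCATTTCG	66.7	49
Rt764_77	TetR family transcriptional regulator	K	2.774	TGAAATCTCCGCAGCCGTTCCA	66.7	40
Rt780_87	AraC family transcriptional regulator	K	2.340	GCAAATCAATCGATCGATCTCG	66.7	117
Rt792_156	LysR family transcriptional regulator	K	2.246	CAGGATCTGGAAGCCGATATCG	66.7	131
Rt641_47	LysR family transcriptional regulator	K	2.237	CGGAAGGTGTTTTCGGATGCCG	66.7	-267
Rt636_12	GntR family transcriptional regulator	K	2.044	CCGAAACTATCAGCGCGCTTCG	66.7	-45
Rt634_21	Transcriptional regulator	K	-1.776	TCAAATCGCTACCCAGATCTTA	66.7	-126
Rt780_42	Membrane protein	S	5.363	CGATATTTAATGATGGATACCA	66.7	-64
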