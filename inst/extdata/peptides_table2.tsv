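protein_id	peptide	prev_aa	next_aa	start	end	working_protease	modifications	abundance_E	abundance_EQ	enzyme	source	row_class	paper_p1_pos	paper_site	paper_domain	paper_log2_abundance	paper_z	eq_higher
P13611-2	GKSPPVR	V	G	27	33	trypsin		978356.00213369843550		ADAMTS9	Table2	semi	26	V26-G27	G1	19.9	17.3	FALSE
P13611-2	TVPSKFTFEEAAK	L	E	256	268	trypsin		6.23331663728400		ADAMTS9	Table2	semi	255	L255-T256	G1	2.64	17.9	FALSE
P13611-2	AEARRGQFE	A	S	440	448	gluc		6.27667278317401		ADAMTS9	Table2	semi	439	A439-A440	GAGbeta	2.65	18.4	FALSE
P13611-2	TEPTGLVLSTVMDRVVAENITQTSR	S	E	893	917	trypsin	1:acetyl	397336.00361130217789		ADAMTS9	Table2	semi	892	S892-T893	GAGbeta	18.6	16.2	FALSE
P13611-2	LWSRQE	K	V	1110	1115	gluc		140479.49128155715880		ADAMTS9	Table2	semi	1109	K1109-L1110	GAGbeta	17.1	3.25	FALSE
P13611-2	EKHPEVPSAK	L	A	1479	1488	trypsin		425854.18438081780914		ADAMTS9	Table2	semi	1478	L1478-E1479	GAGbeta	18.7	16.2	FALSE
P13611-2	INPETQAALIRGQDSTIAASEQQVAARIL	E	D	2023	2051	gluc	3:oxidation	262144.00000000000000		ADAMTS9	Table2	semi	2051	L2051-D2052	GAGbeta	18	17.7	FALSE
P13611-2	LQGAHLT	R	S	2212	2218	trypsin		1825676.85491759423167		ADAMTS9	Table2	semi	2218	T2218-S2219	G3	20.8	2.06	FALSE
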