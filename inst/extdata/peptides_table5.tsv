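protein_id	peptide	prev_aa	next_aa	start	end	working_protease	modifications	abundance_E	abundance_EQ	enzyme	source	row_class	paper_p1_pos	paper_site	paper_domain	paper_log2_abundance	paper_z	eq_higher
P21810	NDISELRK	N	D	100	107	trypsin		2247671.860504915		ADAMTS9	Table5	semi	99	N99-N100	LRR1	21.1	3.6	FALSE
P21810	EISPDTTLLDLQNNDISEL	K	R	87	105	trypsin		456419.213729399		ADAMTS9	Table5	semi	105	L105-R106	LRR2	18.8	6.42	FALSE
P21810	GLQHLYAL	K	V	112	119	trypsin		322737.121091890		ADAMTS9	Table5	semi	119	L119-V120	LRR2	18.3	15.4	FALSE
P21810	PSSLVELR	L	I	158	165	trypsin		22137669.232745551		ADAMTS9	Table5	semi	157	L157-P158	LRR4	24.4	4.47	FALSE
P21810	NHLVEIPPNLPS	K	S	148	159	trypsin		262144.000000000		ADAMTS9	Table5	semi	159	S159-S160	LRR4	18	15.2	FALSE
P21810	NHLVEIPPNLPSS	K	L	148	160	trypsin		1383604.327046597		ADAMTS9	Table5	semi	160	S160-L161	LRR4	20.4	2.45	FALSE
P21810	SLSFLPTLR	G	E	272	280	trypsin		645474.242183780		ADAMTS9	Table5	semi	271	G271-S272	LRR9	19.3	16.2	FALSE
P21810	DNNKLAR	L	V	285	291	trypsin		3178688.028890417		ADAMTS9	Table5	semi	284	L284-D285	LRR9	21.6	18.1	FALSE
P21810	PSGLPDLK	V	L	293	300	trypsin		50859008.462246679		ADAMTS9	Table5	semi	292	V292-P293	LRR10	25.6	8.84	FALSE
P21810	QFGNYK	I	K	362	367	trypsin		456419.213729399		ADAMTS9	Table5	semi	361	I361-Q362	LRR12	18.8	15.7	FALSE
P21810	SVPKEISPDTTLLDLQNNDISE	K	L	83	104	trypsin		370727.600094733		ADAMTS1	Table5	semi	104	E104-L105	LRR2	18.5	2.22	FALSE
P21810	EISPDTTLLDLQNNDISE	K	L	87	104	trypsin		322737.121091890		ADAMTS1	Table5	semi	104	E104-L105	LRR2	18.3	12.8	FALSE
P21810	DDFKGLQH	K	L	108	115	trypsin		456419.213729399		ADAMTS1	Table5	semi	115	H115-L116	LRR2	18.8	2.55	FALSE
P21810	NHLVEIPPNLPSS	K	L	148	160	trypsin		5534417.308186388		ADAMTS1	Table5	semi	160	S160-L161	LRR4	22.4	2.18	FALSE
P21810	NHLVEIPPNLPSSLVE	K	L	148	163	trypsin		23726566.406062890		ADAMTS1	Table5	semi	163	E163-L164	LRR4	24.5	3.78	FALSE
P21810	LRIHDNR	E	I	164	170	trypsin		691802.163523298		ADAMTS1	Table5	semi	163	E163-L164	LRR4	19.4	13.5	FALSE
P21810	FDGLKLNYLR	A	I	205	214	trypsin		1482910.400378931		ADAMTS1	Table5	semi	204	A204-F205	LRR6	20.5	2.18	FALSE
P21810	LHLDHNKIQAIELEDLLR	E	Y	234	251	trypsin		2965820.800757861		ADAMTS1	Table5	semi	233	E233-L234	LRR7	21.5	3.06	FALSE
P21810	DLPETLNELHLD	K	H	226	237	trypsin		691802.163523298		ADAMTS1	Table5	semi	237	D237-H238	LRR7	19.4	2.76	FALSE
P21810	DLPETLNELHLDHNKIQAIELED	K	L	226	248	trypsin		1825676.854917594		ADAMTS1	Table5	semi	248	D248-L249	LRR8	20.8	2.32	FALSE
P21810	RLGLGHNQIR	Y	M	257	266	trypsin		7302707.419670377		ADAMTS1	Table5	semi	256	Y256-R257	LRR8	22.8	4.95	FALSE
P21810	GSLSFLPTLR	N	E	271	280	trypsin		978356.002133698		ADAMTS1	Table5	semi	270	N270-G271	LRR9	19.9	3.03	FALSE
P21810	LRELHLDNNK	T	L	279	288	trypsin		602248.763144685		ADAMTS1	Table5	semi	278	T278-L279	LRR9	19.2	3.5	FALSE
P21810	NHLVEIPPNLPSSLVELRIHDNRIR	K	K	148	172	trypsin			322737.121091890	ADAMTS1	Table5	spanning				18.3	10.9	TRUE
P21810	ISEAKLTGIPKDLPETLNELHLDHNK	R	I	215	240	trypsin			397336.003611302	ADAMTS1	Table5	spanning				18.6	2.07	TRUE
P21810	EKAFSPLR	H	K	131	138	trypsin		2247671.860504915		ADAMTS4	Table5	semi	130	H130-E131	LRR3	21.1	3.17	FALSE
P21810	PKDLPETLNELHLDHNK	I	I	224	240	trypsin		1290948.484367560		ADAMTS4	Table5	semi	223	I223-P224	LRR7	20.3	2.06	FALSE
P21810	SKIHEKAFSPLR	I	K	127	138	trypsin		6813666.950093085		ADAMTS5	Table5	semi	126	I126-S127	LRR3	22.7	2.45	FALSE
P21810	KIHEKAFSPLR	S	K	128	138	trypsin		4495343.721009829		ADAMTS5	Table5	semi	127	S127-K128	LRR3	22.1	3.35	FALSE
P21810	LYISKNHLVEIPPNLPSSLVELRIHD	K	N	143	168	trypsin		1204497.526289370		ADAMTS5	Table5	semi	168	D168-N169	LRR4	20.2	3.02	FALSE
P21810	AKLTGIPK	E	D	218	225	trypsin		741455.200189465		ADAMTS5	Table5	semi	217	E217-A218	LRR6	19.5	2.19	FALSE
P21810	PETLNELHLDHNKIQAIELEDLLRYSK	L	L	228	254	trypsin		978356.002133698		ADAMTS5	Table5	semi	227	L227-P228	LRR7	19.9	2	FALSE
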