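protein_id	peptide	prev_aa	next_aa	start	end	working_protease	modifications	abundance_E	abundance_EQ	enzyme	source	row_class	paper_p1_pos	paper_site	paper_domain	paper_log2_abundance	paper_z	eq_higher
P13611-3	GKSPPVR	V	G	27	33	trypsin		301124.38157234259		ADAMTS1	Table4	semi	26	V26-G27	G1	18.2	14.4	FALSE
P13611-3	GKSPPVRGSLSGK	V	V	27	39	trypsin		978356.00213369844		ADAMTS1	Table4	semi	26	V26-G27	G1	19.9	3.2	FALSE
P13611-3	KSPPVRGSLSGK	G	V	28	39	trypsin		322737.12109188992		ADAMTS1	Table4	semi	27	G27-K28	G1	18.3	3.22	FALSE
P13611-3	VSLPCHF	K	S	40	46	trypsin	1:acetyl	489178.00106684922		ADAMTS1	Table4	semi	46	F46-S47	G1	18.9	15	FALSE
P13611-3	CGGGLLGVR	Q	T	315	323	trypsin		851708.36876163562		ADAMTS1	Table4	semi	314	Q314-C315	G1	19.7	2.37	FALSE
P13611-3	AATVSKWSWDEDNTTSKPLESTEPSAS	E	S	797	823	gluc	18:oxidation;24:oxidation	561917.96512622864		ADAMTS1	Table4	semi	823	S823-S824	GAGalpha	19.1	12.4	FALSE
P13611-3	SQDILVIDQTR	P	L	1001	1011	trypsin		301124.38157234259		ADAMTS1	Table4	semi	1000	P1000-S1001	GAGalpha	18.2	14.4	FALSE
P13611-3	RIGPKVSLSPGPEQKYETE	P	G	1125	1143	gluc		3104.18752821329		ADAMTS1	Table4	semi	1124	P1124-R1125	GAGalpha	11.6	17.7	FALSE
P13611-3	VSLSPGPEQKYE	K	T	1130	1141	gluc		322737.12109188992		ADAMTS1	Table4	semi	1129	K1129-V1130	GAGalpha	18.3	2.34	FALSE
P13611-3	FSTIKVTVPSDITTAFSS	E	V	1196	1213	gluc		345901.08176164923		ADAMTS1	Table4	semi	1213	S1213-V1214	GAGalpha	18.4	2.44	FALSE
P13611-3	FSTIKVTVPSDITTAFSSVDRLHTTSA	E	F	1196	1222	gluc		397336.00361130218		ADAMTS1	Table4	semi	1222	A1222-F1223	GAGalpha	18.6	12.1	FALSE
P13611-3	TVACGQPPVVENAK	G	T	1539	1552	trypsin	1:acetyl;7:oxidation	645474.24218377983		ADAMTS1	Table4	semi	1538	G1538-T1539	G3	19.3	15.2	FALSE
P13611-3	PPVVENAK	Q	T	1545	1552	trypsin		2408995.05257874075		ADAMTS1	Table4	semi	1544	Q1544-P1545	G3	21.2	3.47	FALSE
P13611-3	FSTIKVTVPSDITTAFSSVD	E	R	1196	1215	gluc			262144	ADAMTS1	Table4	spanning				18	2.23	TRUE
P13611-3	DKMGKAGVRTYGFRSPQE	G	T	220	237	gluc		1290948.48436755966		ADAMTS4	Table4	semi	219	G219-D220	G1	20.3	20.7	FALSE
P13611-3	STGIAEKSTLRDSTTE	T	E	888	903	gluc	1:acetyl	44275338.46549110115		ADAMTS4	Table4	semi	887	T887-S888	GAGalpha	25.4	26	FALSE
P13611-3	INSLIRYHCKDGFIQR	E	H	1563	1578	gluc		228209.60686469928		ADAMTS4	Table4	semi	1578	R1578-H1579	G3	17.8	2.05	FALSE
P13611-3	INSLIRYHCKDGFIQRHLPTIR	E	C	1563	1584	gluc		244589.00053342461		ADAMTS4	Table4	semi	1584	R1584-C1585	G3	17.9	18.3	FALSE
P13611-3	INSLIRYHCKDGFIQRHLPTIRCLG	E	N	1563	1587	gluc		1956712.00426739687		ADAMTS4	Table4	semi	1587	G1587-N1588	G3	20.9	3.09	FALSE
P13611-3	CYVDHLDGDVFHLTVPSKFTFEEAAKECENQDAR	Y	L	243	276	trypsin		397336.00361130218		ADAMTS5	Table4	semi	242	Y242-C243	G1	18.6	12.1	FALSE
P13611-3	CYVDHLDGDVFHLTVPSK	Y	F	243	260	trypsin		322737.12109188992		ADAMTS5	Table4	semi	242	Y242-C243	G1	18.3	2.38	FALSE
P13611-3	TVPSKFTFEEAAKE	L	C	256	269	gluc		345901.08176164923		ADAMTS5	Table4	semi	255	L255-T256	G1	18.4	13.8	FALSE
P13611-3	AATVSKWSWDEDNTTSKPLESTEPSAS	E	S	797	823	gluc	18:oxidation;24:oxidation	691802.16352329846		ADAMTS5	Table4	semi	823	S823-S824	GAGalpha	19.4	14.6	FALSE
P13611-3	VEDVDLSKPVSTVPQF	E	A	928	943	gluc		602248.76314468519		ADAMTS5	Table4	semi	943	F943-A944	GAGalpha	19.2	3.33	FALSE
P13611-3	QDILVIDQTRLE	S	A	1002	1013	gluc	1:acetyl	280958.98256311432		ADAMTS5	Table4	semi	1001	S1001-Q1002	GAGalpha	18.1	13.5	FALSE
P13611-3	VLGEPSQDILVI	E	D	996	1007	gluc		3178688.02889041742		ADAMTS5	Table4	semi	1007	I1007-D1008	GAGalpha	21.6	16.2	FALSE
P13611-3	RTWDAAERE	R	C	1434	1442	gluc		172950.54088082461		ADAMTS5	Table4	semi	1433	R1433-R1434	G3	17.4	13	FALSE
P13611-3	LQGAHLT	R	S	1445	1451	trypsin		524288.00000000000		ADAMTS5	Table4	semi	1451	T1451-S1452	G3	19	12.4	FALSE
P13611-3	TVACGQPPVVENAK	G	T	1539	1552	trypsin	1:acetyl;7:oxidation	912838.42745879712		ADAMTS5	Table4	semi	1538	G1538-T1539	G3	19.8	12.9	FALSE
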