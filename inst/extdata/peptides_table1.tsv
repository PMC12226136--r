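protein_id	peptide	prev_aa	next_aa	start	end	working_protease	modifications	abundance_E	abundance_EQ	enzyme	source	row_class	paper_p1_pos	paper_site	paper_domain	paper_log2_abundance	paper_z	eq_higher
Q9P2N4-3	FASSSSSSTSSQAHYR	A	L	86	101	trypsin		228209.606864699		ADAMTS9	Table1	semi	85	A85-F86	Pro	17.8	18.6	FALSE
Q9P2N4-3	VVTMAKRE	F	I	812	819	gluc		244589.000533425		ADAMTS9	Table1	semi	811	F811-V812	Sp	17.9	15	FALSE
Q9P2N4-3	EIRIGNAVVE	R	Y	819	828	gluc		280958.982563114		ADAMTS9	Table1	semi	818	R818-E819	Sp	18.1	15.3	FALSE
Q9P2N4-3	YSGSETAVER	E	I	829	838	trypsin		602248.763144685		ADAMTS9	Table1	semi	828	E828-Y829	Sp	19.2	20.1	FALSE
Q9P2N4-3	LLLQVLSVGK	E	L	849	858	trypsin		456419.213729399		ADAMTS9	Table1	semi	848	E848-L849	Sp	18.8	19.6	FALSE
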