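protein_id	domain_name	start	end
Q9P2N4-3	Pro	30	287
Q9P2N4-3	Mp	288	555
Q9P2N4-3	Dis	556	645
Q9P2N4-3	TSR	646	700
Q9P2N4-3	CR	701	757
Q9P2N4-3	Sp	758	877
P13611-2	G1	1	420
P13611-2	GAGbeta	421	2125
P13611-2	G3	2126	2409
P13611-3	G1	1	420
P13611-3	GAGalpha	421	1345
P13611-3	G3	1346	1642
P21810	LRR1	77	102
P21810	LRR2	103	125
P21810	LRR3	126	147
P21810	LRR4	148	172
P21810	LRR5	173	194
P21810	LRR6	195	221
P21810	LRR7	222	245
P21810	LRR8	246	266
P21810	LRR9	267	290
P21810	LRR10	291	314
P21810	LRR11	315	341
P21810	LRR12	342	368
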