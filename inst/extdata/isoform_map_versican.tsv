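protein_a	start_a	end_a	protein_b	start_b
P13611-3	1	420	P13611-2	1
P13611-3	1346	1642	P13611-2	2113
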