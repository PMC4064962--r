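gene	offset	sequence	conserved
nosR	-73	TGCGTCAACGGCGA	2,4,6,10,12
nosR	-39	CGCGGCCCGGTCGG	2,4,6,10,12
blr2806	-64	CGCGCCTCCGTGGCCG	2,4,6,12,14
blr2806	-49	GGAGGCAGAGCCTG	2,4,6,10,12
norC	-64	CGCGCGAAGCGGC	2,4,11,13
norC	-123	CGTGTCGGCCGTCGT	2,4,6,11,13
bll3466	-78	TGCGACATCGGCGGC	2,4,6,10,12
bll3466	-88	CGAGCCGGAGTGCGAC	2,4,6,12
bll4130	-51	TGCGGCTTTCGTGCC	2,4,6,11
bll4130	-98	TGCGGCAAAGGAGCC	2,4,6,11
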