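gene	locus_tag	span_from	span_to	shift
nosR	blr0314	-195	46	TRUE
cy2	bll2388	-143	31	FALSE
blr2806	blr2806	-214	34	FALSE
norC	blr3214	-149	53	TRUE
bll3466	bll3466	-160	58	TRUE
bll4130	bll4130	-114	61	TRUE
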