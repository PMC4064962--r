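strain	genotype	oxygen	nitrate	activity	se
2499	wild_type	anoxia	FALSE	76.2	6.8
2499	wild_type	anoxia	TRUE	1079	70
2499	wild_type	2% O2	FALSE	39.8	11.3
2499	wild_type	2% O2	TRUE	347.3	52
2499RR	regR	anoxia	FALSE	144	41
2499RR	regR	anoxia	TRUE	28.6	3.9
2499RR	regR	2% O2	FALSE	169.6	25.7
2499RR	regR	2% O2	TRUE	499.5	22.6
2499RS	regS	anoxia	FALSE	nd	nd
2499RS	regS	anoxia	TRUE	1266	90
2499RS	regS	2% O2	FALSE	nd	nd
2499RS	regS	2% O2	TRUE	nd	nd
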