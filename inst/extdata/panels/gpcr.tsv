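gene	protein
Grm1	mGluR1
Grm3	mGluR3
Grm5	mGluR5
Grm7	mGluR7
Grm8	mGluR8
Gabbr1	GABAB1
Gabbr2	GABAB2
Chrm1	M1
Chrm2	M2
Chrm3	M3
Adra1a	alpha1A
Adra2a	alpha2A
Adrb1	beta1
Drd1	D1
Drd2	D2
Htr1a	5-HT1A
Htr2a	5-HT2A
Oprm1	MOR
Oprd1	DOR
Cnr1	CB1
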