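gene	protein
Gria1	GluA1
Gria2	GluA2
Gria3	GluA3
Gria4	GluA4
Grin1	GluN1
Grin2a	GluN2A
Grin2b	GluN2B
Grik2	GluK2
Gabra1	GABAAalpha1
Gabra2	GABAAalpha2
Gabrb2	GABAAbeta2
Gabrb3	GABAAbeta3
Gabrg2	GABAAgamma2
Glra1	GlyRalpha1
Glra2	GlyRalpha2
Glrb	GlyRbeta
Chrna4	nAChRalpha4
Chrna7	nAChRalpha7
Chrnb2	nAChRbeta2
P2rx4	P2X4
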