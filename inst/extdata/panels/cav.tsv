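gene	protein
Cacna1a	Cav2.1
Cacna1b	Cav2.2
Cacna1c	Cav1.2
Cacna1d	Cav1.3
Cacna1e	Cav2.3
Cacna1g	Cav3.1
Cacna1h	Cav3.2
Cacna1i	Cav3.3
Cacna2d1	Cavalpha2delta1
Cacnb1	Cavbeta1
Cacnb2	Cavbeta2
Cacnb3	Cavbeta3
Cacnb4	Cavbeta4
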