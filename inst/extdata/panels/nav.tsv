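gene	protein
Scn1a	Nav1.1
Scn2a	Nav1.2
Scn3a	Nav1.3
Scn8a	Nav1.6
Scn1b	Navbeta1
Scn2b	Navbeta2
Scn3b	Navbeta3
Scn4b	Navbeta4
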