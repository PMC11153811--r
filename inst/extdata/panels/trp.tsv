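gene	protein
Trpc1	TRPC1
Trpc3	TRPC3
Trpc4	TRPC4
Trpc5	TRPC5
Trpm2	TRPM2
Trpm3	TRPM3
Trpm4	TRPM4
Trpm7	TRPM7
Trpv1	TRPV1
Trpv2	TRPV2
Trpv4	TRPV4
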