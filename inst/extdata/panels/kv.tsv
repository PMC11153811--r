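gene	protein
Kcna1	Kv1.1
Kcna2	Kv1.2
Kcna4	Kv1.4
Kcna6	Kv1.6
Kcnb1	Kv2.1
Kcnb2	Kv2.2
Kcnc1	Kv3.1
Kcnc2	Kv3.2
Kcnc3	Kv3.3
Kcnc4	Kv3.4
Kcnd2	Kv4.2
Kcnd3	Kv4.3
Kcnq2	Kv7.2
Kcnq3	Kv7.3
Kcnq4	Kv7.4
Kcnq5	Kv7.5
Kcnh1	Kv10.1
Kcnh2	Kv11.1
Kcnab1	Kvbeta1
Kcnab2	Kvbeta2
Kcnab3	Kvbeta3
Kcne1	MinK
Kcne2	MiRP1
Kcnip1	KChIP1
Kcnip2	KChIP2
Kcnip3	KChIP3
Kcnip4	KChIP4
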