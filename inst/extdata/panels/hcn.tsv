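gene	protein
Hcn1	HCN1
Hcn2	HCN2
Hcn3	HCN3
Hcn4	HCN4
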