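gene	protein
Slc17a6	vGLUT2
Slc6a5	GlyT2
Gad2	GAD65
Ddc	DDC
Chat	ChAT
Calca	CGRP
Ucn	Urocortin
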