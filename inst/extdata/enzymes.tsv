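name	recognition	cut_offset
AluI	AGCT	2
BfaI	CTAG	1
HaeIII	GGCC	2
HhaI	GCGC	3
HinfI	GANTC	1
MspI	CCGG	1
RsaI	GTAC	2
Sau3AI	GATC	0
TaqI	TCGA	1
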