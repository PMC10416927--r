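pathway	gene
RTK/RAS	EGFR
RTK/RAS	FGFR1
RTK/RAS	ERBB2
RTK/RAS	FGFR2
RTK/RAS	FGFR3
RTK/RAS	PDGFRA
RTK/RAS	KRAS
RTK/RAS	HRAS
Nrf2	KEAP1
Nrf2	NFE2L2
TGFb	ACVR2A
TGFb	SMAD4
PI3K	PTEN
PI3K	PIK3CA
PI3K	PIK3R1
PI3K	AKT1
PI3K	STK11
p53	MDM2
p53	CDKN2A
p53	TP53
Cell cycle	CDKN2A
Cell cycle	CDKN2B
Cell cycle	CCNE1
Cell cycle	CCND1
Cell cycle	CDK4
Cell cycle	RB1
Cell cycle	E2F3
Notch	NOTCH1
Notch	FBXW7
Notch	EP300
Hippo	DCHS2
Hippo	FAT1
Hippo	NF2
Wnt	RNF43
Wnt	APC
Wnt	CTNNB1
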