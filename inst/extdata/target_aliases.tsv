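alias	hgnc_symbol
VEGF	VEGFA
VEGFR1	FLT1
VEGFR2	KDR
VEGFR3	FLT4
PDGFR-alpha	PDGFRA
PDGFR-beta	PDGFRB
TIE2	TEK
TrkA	NTRK1
Eph2A	EPHA2
RAF-1	RAF1
Abl	ABL1
SAPK2	MAPK14
PTK5	FRK
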