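drug	targets	status
bevacizumab	VEGF	approved
aflibercept	VEGFA,VEGFB,PGF	approved
bortezomib	PSMB5,PSMB1	off_label
cabozantinib	MET,KDR	off_label
cetuximab	EGFR	approved
crizotinib	ALK,MET	off_label
panitumumab	EGFR	approved
regorafenib	RET,VEGFR1,VEGFR2,VEGFR3,KIT,PDGFR-alpha,PDGFR-beta,FGFR1,FGFR2,TIE2,DDR2,TrkA,Eph2A,RAF-1,BRAF,SAPK2,PTK5,Abl	approved
denosumab	TNFSF11	off_label
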