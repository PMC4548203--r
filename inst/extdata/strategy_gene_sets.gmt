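GO:0016525	negative regulation of angiogenesis	AMOT	ANGPT2	APOH	BAI1	CCL2	CCR2	COL4A2	COL4A3	CXCL10	FASLG	FOXO4	GHRL	GTF2I	HDAC5	HHEX	HOXA5	HRG	KLF4	KLK3	KRIT1	LECT1	LIF	MAP2K5	NF1	NPPB	NPR1	PDE3B	PF4	PML	PTPRM	ROCK1	ROCK2	SERPINE1	SERPINF1	STAB1	THBS1	THBS2	THBS4	TIE1
GO:0050729	positive regulation of inflammatory response	ACE	ADAM8	ADORA2B	ADORA3	AGER	AGT	AGTR1	ALOX5AP	AOC3	C3	CCL24	CCL3	CCL3L3	CCL5	CCR2	CCR5	CCR7	CD28	CD47	CLOCK	CNR1	CTSS	CX3CL1	EDNRA	EGFR	FABP4	FCER1A	FCER1G	FCGR1A	FCGR2A	FFAR3	GPRC5B	HSPD1	HYAL2	IDO1	IL12B	IL15	IL18	IL1B	IL1RL1	IL2	IL21	IL23A	IL33	IL6	IL6ST	ITGA2	JAK2	LBP	LTA	MAPK13	MIF	NLRP12	NPY5R	OSM	OSMR	PDE2A	PDE5A	PIK3CG	PLA2G2A	PLA2G4A	PLA2G7	PRKCA	PTGER3	PTGER4	PTGS2	RPS19	S100A12	S100A8	S100A9	SERPINE1	STAT5A	STAT5B	TAC1	TGM2	TLR2	TLR3	TLR4	TLR7	TLR9	TLR10	TNF	TNFRSF11A	TNFRSF1A	TNFSF11	TNFSF4	TNIP1	WNT5A	ZP3
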