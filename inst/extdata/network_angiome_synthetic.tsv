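# Synthetic angiome-like stand-in network (SERPINE1 hub, degree 14).
SERPINE1	PLAT
SERPINE1	PLAU
SERPINE1	PLG
SERPINE1	F2
SERPINE1	FN1
SERPINE1	VTN
SERPINE1	TGFB1
SERPINE1	VEGFA
SERPINE1	EGF
SERPINE1	IGF1
SERPINE1	IL6
SERPINE1	TNF
SERPINE1	CCL2
SERPINE1	NPPB
PLAT	PLAU
PLAU	PLG
TNF	IL6
CCL2	IL6
VEGFA	FN1
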