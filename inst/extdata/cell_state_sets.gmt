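M1	macrophage classical activation	TNF	IL1B	IL6	IL12B	CXCL9	CXCL10	CXCL11	CD80	CD86	NOS2	FCGR1A	SOCS3
M2	macrophage alternative activation	MRC1	CD163	MSR1	CCL22	CCL17	IL10	TGFB1	STAB1	MAF	LYVE1
angiogenesis	pro-angiogenic program	VEGFA	VEGFB	FLT1	KDR	TEK	ANGPT1	ANGPT2	HIF1A	PDGFB	CXCL8
phagocytosis	phagocytic program	MRC1	CD163	MERTK	AXL	C1QA	C1QB	C1QC	MARCO	CD36	GAS6
naive	T-cell naive program	CCR7	SELL	TCF7	LEF1	IL7R	CD27	CD28	BACH2
activation	T-cell activation program	CD69	IL2RA	TNFRSF9	TNFRSF4	ICOS	CD40LG	MKI67
cytotoxicity	T-cell cytotoxic program	GNLY	GZMB	GZMA	GZMH	PRF1	NKG7	KLRD1	FGFBP2	KLF2	CTSW
exhaustion	T-cell exhaustion program	PDCD1	CTLA4	HAVCR2	LAG3	TIGIT	TOX	CXCL13	ENTPD1	LAYN
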