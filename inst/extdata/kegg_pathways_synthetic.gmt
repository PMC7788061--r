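hsa04658	Th1 and Th2 cell differentiation	IFNG	IL4	IL2	STAT1	STAT4	STAT6	GATA3	TBX21	IL12RB1	RUNX3
hsa04612	Antigen processing and presentation	HLA-A	HLA-B	HLA-C	HLA-DRA	HLA-DRB1	HLA-DQA1	TAP1	TAP2	B2M	PSMB8
hsa04640	Hematopoietic cell lineage	CD34	CD38	IL3RA	KIT	FLT3	CSF1R	CD19	MS4A1	ITGA2B	EPOR
hsa04659	Th17 cell differentiation	IL17A	IL17F	RORC	RORA	IL21	IL23R	STAT3	IL6R	TGFBR1	FOXP3
hsa04672	Intestinal immune network for IgA production	TNFSF13	TNFSF13B	AICDA	CCR9	CCR10	ITGB7	MADCAM1	PIGR	IL10	TGFB1
hsa04650	Natural killer cell mediated cytotoxicity	KLRD1	KLRC1	NCR1	NCR3	PRF1	GZMB	FASLG	KIR2DL1	KIR3DL1	FCGR3A
hsa04668	TNF signalling pathway	TNF	TNFRSF1A	TNFRSF1B	TRADD	TRAF2	RIPK1	MAP3K7	NFKB1	CASP8	CFLAR
hsa04630	JAK-STAT signalling pathway	JAK1	JAK2	JAK3	TYK2	STAT1	STAT2	STAT3	STAT5A	SOCS1	IFNK
hsa04622	RIG-I-like receptor signalling pathway	DDX58	IFIH1	DHX58	MAVS	IRF3	IRF7	TBK1	IKBKE	TRAF3	ISG15
hsa04621	NOD-like receptor signalling pathway	NOD1	NOD2	NLRP1	NLRP3	NLRC4	CASP1	PYCARD	IL1B	IL18	RIPK2
hsa04610	Complement and coagulation cascades	C1QA	C1QB	C1QC	C1R	C1S	C2	C3	C4A	C4B	CFB
hsa04620	Toll-like receptor signalling pathway	TLR1	TLR2	TLR4	TLR5	TLR7	TLR8	TLR9	MYD88	TICAM1	IRAK4
hsa04060	Cytokine-cytokine receptor interaction	IL1A	IL1B	IL2	IL6	IL10	IL12A	IL12B	TNF	IFNG	CXCL8
hsa04625	C-type lectin receptor signalling pathway	CLEC7A	CLEC4E	CLEC6A	SYK	CARD9	BCL10	MALT1	PLCG2	RAF1	STAT1
hsa04657	IL-17 signalling pathway	IL17A	IL17F	IL17RA	IL17RC	ACT1	TRAF6	NFKB1	MAPK1	CXCL1	CSF3
hsa04664	Fc epsilon RI signalling pathway	FCER1A	FCER1G	MS4A2	LYN	SYK	LAT	PLCG1	PRKCA	MAPK3	TNF
hsa04061	Viral protein interaction with cytokine and cytokine receptor	CCL2	CCL5	CXCL8	CXCL10	CCR1	CCR5	CXCR3	CXCR4	IL10	TNFRSF14
hsa04064	NF-kappa B signalling pathway	NFKB1	NFKB2	RELA	RELB	REL	NFKBIA	IKBKB	CHUK	IKBKG	TRAF6
hsa04380	Osteoclast differentiation	TNFSF11	TNFRSF11A	CSF1	CSF1R	FOS	JUN	NFATC1	SPI1	TYROBP	TREM2
hsa04660	T cell receptor signalling pathway	CD3D	CD3E	CD3G	CD4	CD8A	LCK	ZAP70	LAT	PTPN22	CTLA4
hsa04623	Cytosolic DNA-sensing pathway	CGAS	TMEM173	TBK1	IRF3	IRF7	DDX41	POLR3A	AIM2	PYCARD	IL1B
hsa04662	B cell receptor signalling pathway	CD79A	CD79B	BLK	LYN	SYK	BTK	BLNK	PLCG2	CD19	BANK1
hsa04062	Chemokine signalling pathway	CCL2	CCL5	CXCL12	CXCR4	CCR2	CCR5	GNAI2	PIK3CG	PRKCB	STAT3
hsa04611	Platelet activation	ITGA2B	ITGB3	GP1BA	GP6	F2R	P2RY12	PLCB3	PRKACA	VWF	FGA
hsa04666	Fc gamma R-mediated phagocytosis	FCGR1A	FCGR2A	FCGR2B	FCGR3A	SYK	PLCG2	PRKCE	RAC1	CDC42	WASF2
hsa04670	Leukocyte transendothelial migration	ICAM1	VCAM1	PECAM1	CDH5	ITGAL	ITGAM	ITGB2	CXCL12	CXCR4	MMP9
hsa04514	Cell adhesion molecules	HLA-DRB1	HLA-DQB1	CD28	CTLA4	ICOS	CD86	PDCD1	CD274	ITGAL	ICAM1
hsa04151	PI3K-Akt signalling pathway	PIK3CA	PIK3CD	PIK3R1	AKT1	AKT2	PTEN	MTOR	GSK3B	FOXO3	TP53
hsa04010	MAPK signalling pathway	MAP2K1	MAP2K4	MAPK1	MAPK3	MAPK8	MAPK14	RAF1	KRAS	NRAS	DUSP1
hsa04020	Calcium signalling pathway	CACNA1C	ITPR1	RYR2	PLCB1	PLCG1	CAMK2G	CALM1	PPP3CA	NFATC1	PRKCA
hsa04066	HIF-1 signalling pathway	HIF1A	EPAS1	VHL	EGLN1	ARNT	VEGFA	EPO	SLC2A1	PIK3CA	MTOR
hsa04150	mTOR signalling pathway	MTOR	RPTOR	RICTOR	AKT1	TSC1	TSC2	RHEB	EIF4EBP1	RPS6KB1	ULK1
hsa04210	Apoptosis	CASP3	CASP8	CASP9	BAX	BCL2	FAS	FASLG	APAF1	CYCS	BID
hsa04217	Necroptosis	RIPK1	RIPK3	MLKL	ZBP1	TNF	FADD	CASP8	CFLAR	PGAM5	IFNAR1
hsa04350	TGF-beta signalling pathway	TGFB1	TGFB2	TGFBR1	TGFBR2	SMAD2	SMAD3	SMAD4	SMAD7	BMP2	INHBA
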