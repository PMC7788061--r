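IFN_TYPE_I	Type I interferon pathway (literature set)	IFNA1	IFNA2	IFNA21	IFNB1	IFNK	IFNAR1	IFNAR2	TYK2	JAK1	STAT1	STAT2	IRF3	IRF7	IRF9	MX1	OAS1
INTERFERONOPATHY	Interferonopathy genes (literature set)	TREX1	RNASEH2A	RNASEH2B	RNASEH2C	SAMHD1	ADAR	IFIH1	TMEM173	DNASE2	USP18	ISG15
SLE_GWAS	SLE genome-wide association study genes (literature set)	STAT4	IRF5	TNIP1	ITGAM	BLK	BANK1	PTPN22	TNFSF4	IRAK1	TLR7	FCGR2A	HLA-DRB1	TNFAIP3	IKZF1	ETS1	UBE2L3
COMPLEMENT	Complement subset of KEGG hsa04610 (literature set)	C1QA	C1QB	C1QC	C1R	C1S	C2	C3	C4A	C4B	CFB	CFH	CFI
MONOGENIC_SLE	Genes for monogenic SLE and lupus-like disease (literature set)	TREX1	DNASE1	DNASE1L3	C1QA	C1QB	C1QC	C1R	C1S	C2	C4A	C4B	PRKCD	ACP5	SAMHD1	RNASEH2A	FASLG
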