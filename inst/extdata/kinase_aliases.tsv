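alias	symbol	family
CHUK	CHUK	IKK
IKKA	CHUK	IKK
IKK-alpha	CHUK	IKK
IKBKB	IKBKB	IKK
IKKB	IKBKB	IKK
IKBKE	IKBKE	IKK
IKKE	IKBKE	IKK
TBK1	TBK1	IKK
NAK	TBK1	IKK
PRKD1	PRKD1	PKD
PKD1	PRKD1	PKD
PKCM	PRKD1	PKD
PRKD2	PRKD2	PKD
PKD2	PRKD2	PKD
PRKD3	PRKD3	PKD
PKD3	PRKD3	PKD
CAMK2A	CAMK2A	CAMK2
KIAA0968	CAMK2A	CAMK2
CAMK2B	CAMK2B	CAMK2
CAMK2D	CAMK2D	CAMK2
CAMK2G	CAMK2G	CAMK2
MAPK1	MAPK1	ERK
ERK2	MAPK1	ERK
MAPK3	MAPK3	ERK
ERK1	MAPK3	ERK
MAPK8	MAPK8	JNK
JNK1	MAPK8	JNK
MAPK9	MAPK9	JNK
JNK2	MAPK9	JNK
MAPK10	MAPK10	JNK
JNK3	MAPK10	JNK
MAPK14	MAPK14	P38
P38A	MAPK14	P38
MAPK11	MAPK11	P38
P38B	MAPK11	P38
RIPK1	RIPK1	RIPK
RIP1	RIPK1	RIPK
RIPK2	RIPK2	RIPK
RIP2	RIPK2	RIPK
RIPK3	RIPK3	RIPK
PRKACA	PRKACA	PKA
PKACA	PRKACA	PKA
PRKACB	PRKACB	PKA
PRKCA	PRKCA	PKC
PKCA	PRKCA	PKC
PRKCB	PRKCB	PKC
PRKCD	PRKCD	PKC
AKT1	AKT1	AKT
PKB	AKT1	AKT
AKT2	AKT2	AKT
AKT3	AKT3	AKT
GSK3A	GSK3A	GSK3
GSK3B	GSK3B	GSK3
CSNK2A1	CSNK2A1	CK2
CK2A1	CSNK2A1	CK2
CSNK2A2	CSNK2A2	CK2
CSK	CSK	CSK
MATK	MATK	CSK
HYL	MATK	CSK
EGFR	EGFR	EGFR
ERBB1	EGFR	EGFR
HER1	EGFR	EGFR
ERBB2	ERBB2	EGFR
HER2	ERBB2	EGFR
ERBB4	ERBB4	EGFR
HER4	ERBB4	EGFR
PTK2	PTK2	FAK
FAK	PTK2	FAK
FAK1	PTK2	FAK
PTK2B	PTK2B	FAK
PYK2	PTK2B	FAK
FLT1	FLT1	VEGFR
VEGFR1	FLT1	VEGFR
KDR	KDR	VEGFR
VEGFR2	KDR	VEGFR
FLT4	FLT4	VEGFR
VEGFR3	FLT4	VEGFR
SRC	SRC	SRC
FYN	FYN	SRC
LCK	LCK	SRC
LYN	LYN	SRC
ABL1	ABL1	ABL
ABL	ABL1	ABL
ABL2	ABL2	ABL
ARG	ABL2	ABL
JAK1	JAK1	JAK
JAK2	JAK2	JAK
JAK3	JAK3	JAK
TYK2	TYK2	JAK
SYK	SYK	SYK
ZAP70	ZAP70	SYK
RYK	RYK	RYK
JTK5	RYK	RYK
INSR	INSR	INSR
IGF1R	IGF1R	INSR
PDGFRA	PDGFRA	PDGFR
PDGFRB	PDGFRB	PDGFR
KIT	KIT	PDGFR
EPHA1	EPHA1	EPH
EPHA2	EPHA2	EPH
EPHB1	EPHB1	EPH
EPHB2	EPHB2	EPH
FGFR1	FGFR1	FGFR
FGFR2	FGFR2	FGFR
FGFR3	FGFR3	FGFR
MET	MET	MET
HGFR	MET	MET
MST1R	MST1R	MET
RON	MST1R	MET
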