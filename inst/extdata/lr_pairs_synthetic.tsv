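ligand	receptor
SEMA4A	NRP1
BMP7	BMPR1A+ACVR2A
WNT5A	ROR1
SPP1	ITGAV
C3	CD46
PDGFA	PDGFRA
MLLT4	EPHB6
GAS6	MERTK
INHBB	ACVR1C+ACVR2B
FIGF	NRP2
NRG2	ERBB3
CYR61	ITGB5
COL7A1	ITGB1
SPTAN1	PTPRA
SST	SSTR2
EFNA3	EPHA6
RSPO3	FZD8
BDNF	NTRK2
NGF	NGFR
VEGFA	FLT4
EFNB2	EPHB4
DLL1	NOTCH3
JAG2	NOTCH1
CX3CL1	CX3CR1
CSF1	CSF1R
IL34	PTPRZ1
TGFB2	TGFBR3
GDF11	ACVR1B+TGFBR1
ANGPT1	TEK
SLIT2	ROBO2
NTN1	DCC
RELN	LRP8
SHH	PTCH1
WNT3A	FZD1+LRP6
CCL2	CCR2
CXCL12	CXCR4
PTN	ALK
MDK	SDC3
HBEGF	EGFR
NRG1	ERBB4
EFNA5	EPHA4
SEMA3A	PLXNA1
SEMA6D	PLXNA4
APOE	LRP1
CLU	TREM2
TNF	TNFRSF1B
IL6	IL6R
LIF	LIFR+IL6ST
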