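cell_type	gene
astrocytes	GFAP
astrocytes	AQP4
astrocytes	SLC1A2
astrocytes	ALDH1L1
astrocytes	GJA1
endothelial cells	CLDN5
endothelial cells	FLT1
endothelial cells	PECAM1
endothelial cells	VWF
endothelial cells	A2M
microglia	CX3CR1
microglia	CSF1R
microglia	P2RY12
microglia	AIF1
microglia	TMEM119
neurons	SLC17A7
neurons	SNAP25
neurons	RBFOX3
neurons	SYT1
neurons	GAD1
OPC	PDGFRA
OPC	CSPG4
OPC	OLIG1
OPC	VCAN
OPC	LHFPL3
oligodendrocytes	MAG
oligodendrocytes	OLIG2
oligodendrocytes	MBP
oligodendrocytes	MOG
oligodendrocytes	PLP1
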