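treatment	direction	gene
naturally_occurring	up	EP300
naturally_occurring	up	IQGAP1
naturally_occurring	up	MAP3K14
naturally_occurring	up	MAP3K3
naturally_occurring	up	NCF2
naturally_occurring	up	PIK3R5
naturally_occurring	up	PRKCD
naturally_occurring	up	PTGES
naturally_occurring	up	RAD23A
naturally_occurring	up	RIPK2
naturally_occurring	up	TAB1
naturally_occurring	down	AKT1
naturally_occurring	down	CDC42
naturally_occurring	down	DUSP7
naturally_occurring	down	GSK3B
naturally_occurring	down	HGF
naturally_occurring	down	NCF1
naturally_occurring	down	TAOK1
naturally_occurring	down	TGFB2
naturally_occurring	down	TRAF6
desialylated	up	EP300
desialylated	up	CASP2
desialylated	up	DUSP5
desialylated	up	IQGAP1
desialylated	up	PIK3R5
desialylated	up	PTGES
desialylated	up	PRKCD
desialylated	up	PRKCB
desialylated	up	RAD23A
desialylated	up	RIPK2
desialylated	down	DUSP7
desialylated	down	HGF
desialylated	down	MAP2K5
desialylated	down	MAP2K7
desialylated	down	NCF1
desialylated	down	TGFB2
desialylated	down	TGFB3
desialylated	down	TRADD
desialylated	down	TRAF6
acetylated	up	NCF2
acetylated	up	PRKCD
acetylated	up	PTGES
acetylated	up	SGK1
acetylated	down	AKT1
acetylated	down	CASP8
acetylated	down	DUSP1
acetylated	down	DUSP16
acetylated	down	GSK3B
acetylated	down	HDAC3
acetylated	down	IL1A
acetylated	down	MAP2K1
acetylated	down	MAP3K1
acetylated	down	MAP4K2
acetylated	down	OTUB1
acetylated	down	TAOK1
acetylated	down	TRADD
acetylated	down	TRAF6
oxidized	up	CASP2
oxidized	up	IQGAP1
oxidized	up	MAP3K14
oxidized	up	NCF2
oxidized	up	PRKCB
oxidized	up	RAD23A
oxidized	up	SGK1
oxidized	down	AKT1
oxidized	down	CDC42
oxidized	down	DUSP1
oxidized	down	DUSP16
oxidized	down	GSK3B
oxidized	down	HDAC3
oxidized	down	KRAS
oxidized	down	MAP3K1
oxidized	down	MAP4K2
oxidized	down	MAPK8IP1
oxidized	down	NCF1
oxidized	down	TAOK1
oxidized	down	TRAF6
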