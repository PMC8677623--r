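ligand	receptor	family
EFNA1	EPHA2	Ephrin
EFNA5	EPHA4	Ephrin
EFNB1	EPHB2	Ephrin
EFNB2	EPHB4	Ephrin
EFNB2	EPHA4	Ephrin
EFNB3	EPHB6	Ephrin
FGF1	FGFR1	FGF
FGF2	FGFR1	FGF
FGF2	FGFR2	FGF
FGF7	FGFR2	FGF
FGF9	FGFR3	FGF
FGF10	FGFR2	FGF
FGF18	FGFR3	FGF
WNT2	FZD1	WNT
WNT2B	FZD4	WNT
WNT3A	FZD1	WNT
WNT5A	FZD2	WNT
WNT5A	FZD5	WNT
WNT7B	FZD10	WNT
WNT11	FZD7	WNT
TGFB1	TGFBR1+TGFBR2	TGFb
TGFB2	TGFBR1+TGFBR2	TGFb
TGFB3	TGFBR1+TGFBR2	TGFb
INHBA	ACVR1B+ACVR2A	TGFb
GDF15	TGFBR2	TGFb
BMP2	BMPR1A+BMPR2	BMP
BMP4	BMPR1A+BMPR2	BMP
BMP5	BMPR1B+BMPR2	BMP
BMP6	ACVR1+BMPR2	BMP
BMP7	BMPR1B+ACVR2A	BMP
IL6	IL6R+IL6ST	JAK/STAT
IL11	IL11RA+IL6ST	JAK/STAT
LIF	LIFR+IL6ST	JAK/STAT
OSM	OSMR+IL6ST	JAK/STAT
IL10	IL10RA+IL10RB	JAK/STAT
IFNG	IFNGR1+IFNGR2	JAK/STAT
CSF1	CSF1R	JAK/STAT
CXCL12	CXCR4	JAK/STAT
HGF	MET	RTK
VEGFA	KDR	RTK
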