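gene,family,role,probe_sets,receptor_of,known_mgf
IGF1,OTHER,LIGAND,209541_at,,1
HGF,OTHER,LIGAND,210997_at,,1
CCL3,OTHER,LIGAND,205114_s_at,,1
GDF15,OTHER,LIGAND,221577_x_at,,1
PTN,OTHER,LIGAND,209466_x_at,,1
BDNF,OTHER,LIGAND,206382_s_at,,1
IL6,IL6_FAMILY,LIGAND,205207_at,,1
CNTF,IL6_FAMILY,LIGAND,,,1
OSM,IL6_FAMILY,LIGAND,230170_at,,1
LIF,IL6_FAMILY,LIGAND,205266_at,,1
IL11,IL6_FAMILY,LIGAND,,,1
CLCF1,IL6_FAMILY,LIGAND,219500_at,,1
IL1B,OTHER,LIGAND,39402_at,,1
IL10,OTHER,LIGAND,207433_at,,1
IL15,OTHER,LIGAND,205992_s_at,,1
IL21,OTHER,LIGAND,,,1
TNF,TNF,LIGAND,207113_s_at,,1
TNFSF13B,TNF,LIGAND,223501_at,,1
TNFSF13,TNF,LIGAND,210314_x_at,,1
AREG,EGF,LIGAND,205239_at,,1
HBEGF,EGF,LIGAND,203821_at,,1
NRG1,EGF,LIGAND,208241_at,,1
NRG2,EGF,LIGAND,206879_s_at,,1
NRG3,EGF,LIGAND,229233_at,,1
NRG4,EGF,LIGAND,242426_at,,1
JAG1,OTHER,LIGAND,209099_x_at,,1
JAG2,OTHER,LIGAND,32137_at,,1
VEGFA,VEGF,LIGAND,212171_x_at,,1
VEGFB,VEGF,LIGAND,203683_s_at,,0
VEGFC,VEGF,LIGAND,209946_at,,0
VEGFD,VEGF,LIGAND,,,0
FGF1,FGF,LIGAND,1552721_a_at,,0
FGF2,FGF,LIGAND,204422_s_at,,1
FGF3,FGF,LIGAND,214571_at,,0
FGF4,FGF,LIGAND,206783_at,,0
FGF5,FGF,LIGAND,210311_at,,0
FGF6,FGF,LIGAND,208417_at,,0
FGF7,FGF,LIGAND,230918_at,,0
FGF8,FGF,LIGAND,,,0
FGF9,FGF,LIGAND,206404_at,,0
FGF10,FGF,LIGAND,,,0
FGF11,FGF,LIGAND,227271_at,,0
FGF12,FGF,LIGAND,1562794_at,,0
FGF13,FGF,LIGAND,205110_s_at,,0
FGF14,FGF,LIGAND,231523_at,,0
FGF16,FGF,LIGAND,,,0
FGF17,FGF,LIGAND,,,0
FGF18,FGF,LIGAND,231382_at,,0
FGF19,FGF,LIGAND,,,0
FGF20,FGF,LIGAND,,,0
FGF21,FGF,LIGAND,,,0
FGF22,FGF,LIGAND,,,0
FGF23,FGF,LIGAND,,,0
Wnt1,WNT,LIGAND,,,0
Wnt2,WNT,LIGAND,205648_at,,0
Wnt2B,WNT,LIGAND,,,0
Wnt3,WNT,LIGAND,229103_at,,0
Wnt3A,WNT,LIGAND,,,0
Wnt4,WNT,LIGAND,208606_s_at,,0
Wnt5A,WNT,LIGAND,205990_s_at,,1
Wnt5B,WNT,LIGAND,221029_s_at,,0
Wnt6,WNT,LIGAND,71933_at,,0
Wnt7A,WNT,LIGAND,210248_at,,0
Wnt7B,WNT,LIGAND,,,0
Wnt8A,WNT,LIGAND,224259_at,,0
Wnt8B,WNT,LIGAND,,,0
Wnt9A,WNT,LIGAND,,,0
Wnt9B,WNT,LIGAND,,,0
Wnt10A,WNT,LIGAND,223709_s_at,,0
Wnt10B,WNT,LIGAND,,,1
Wnt11,WNT,LIGAND,206737_at,,0
Wnt16,WNT,LIGAND,224022_x_at,,1
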