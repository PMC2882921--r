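gene,family,role,probe_sets,receptor_of,median_mmc,range_min,range_max,presence_pct
IGF1R,OTHER,RECEPTOR,203627_at,IGF1,19,1,85,32
MET,OTHER,RECEPTOR,203510_at,HGF,78,4,728,50
CCR1,OTHER,RECEPTOR,205098_at,CCL3,136,26,2840,78
PTPRZ1,OTHER,RECEPTOR,204469_at,PTN,24,1,1958,48
NTRK2,OTHER,RECEPTOR,207152_at,BDNF,84,4,286,77
IL6R,IL6_FAMILY,RECEPTOR,205945_at,IL6,502,7,3657,99
IL6ST,IL6_FAMILY,RECEPTOR,212195_at,IL6,1681,210,5680,100
CNTFR,IL6_FAMILY,RECEPTOR,,CNTF,,,,
OSMR,IL6_FAMILY,RECEPTOR,205729_at,OSM,25,1,88,58
LIFR,IL6_FAMILY,RECEPTOR,225575_at,LIF,16,1,203,15
IL11RA,IL6_FAMILY,RECEPTOR,204773_at,IL11,61,3,140,26
CRLF1,IL6_FAMILY,RECEPTOR,206315_at,CLCF1,15,2,91,0
IL1R1,OTHER,RECEPTOR,202948_at,IL1B,10,1,63,1
IL10RA,OTHER,RECEPTOR,204912_at,IL10,212,24,912,92
IL10RB,OTHER,RECEPTOR,209575_at,IL10,240,98,536,100
IL15RA,OTHER,RECEPTOR,207375_s_at,IL15,142,16,403,55
IL21R,OTHER,RECEPTOR,221658_s_at,IL21,6,1,395,5
TNFRSF1A,TNF,RECEPTOR,241944_x_at,TNF,63,4,233,66
TNFRSF13B,TNF,RECEPTOR,207641_at,TNFSF13B,266,50,745,95
TNFRSF13C,TNF,RECEPTOR,,TNFSF13B,,,,
TNFRSF17,TNF,RECEPTOR,206641_at,TNFSF13,3794,968,8301,100
ERBB1,EGF,RECEPTOR,211551_at,AREG,56,6,148,64
ERBB2,EGF,RECEPTOR,216836_s_at,AREG,30,2,106,5
ERBB3,EGF,RECEPTOR,202454_s_at,NRG1,47,79,172,59
ERBB4,EGF,RECEPTOR,214053_at,NRG1,51,2,1091,38
FLT1,VEGF,RECEPTOR,,VEGFA,,,,
KDR,VEGF,RECEPTOR,,VEGFA,,,,
FLT4,VEGF,RECEPTOR,,VEGFC,,,,
FGFR1,FGF,RECEPTOR,,FGF2,,,,
FGFR2,FGF,RECEPTOR,,FGF2,,,,
FGFR3,FGF,RECEPTOR,204379_s_at,FGF2,4.2,1,13160,10
FGFR4,FGF,RECEPTOR,,FGF2,,,,
FZD1,WNT,RECEPTOR,204451_at,Wnt5A,75,2,586,34
FZD2,WNT,RECEPTOR,210220_at,Wnt5A,30,1,680,30
FZD3,WNT,RECEPTOR,219683_at,Wnt5A,80,15,465,19
FZD4,WNT,RECEPTOR,218665_at,Wnt5A,84,2,348,92
FZD5,WNT,RECEPTOR,,Wnt5A,,,,
FZD6,WNT,RECEPTOR,203987_at,Wnt5A,229,6,1425,
FZD7,WNT,RECEPTOR,203706_s_at,Wnt5A,102,12,2228,98
FZD8,WNT,RECEPTOR,227405_s_at,Wnt5A,34,3,338,93
FZD9,WNT,RECEPTOR,,Wnt5A,,,,
FZD10,WNT,RECEPTOR,,Wnt5A,,,,
LRP5,WNT,RECEPTOR,,Wnt5A,,,,
LRP6,WNT,RECEPTOR,225745_at,Wnt5A,70,1,137,43
NOTCH1,OTHER,RECEPTOR,218902_at,JAG1,85,24,233,47
NOTCH2,OTHER,RECEPTOR,212377_s_at,JAG1,216,43,1743,100
NOTCH3,OTHER,RECEPTOR,203238_s_at,JAG1,28,1.4,95,2
NOTCH4,OTHER,RECEPTOR,205247_at,JAG1,40,8,190,35
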