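PTGS2
STK11
MEN1
AKT1
PARK2
CDH1
BRCA1
IGF1R
BRCA2
MUC4
KRAS
ROBO2
PTEN
ARID1A
HRAS
HIF1A
XRCC1
NR5A2
VEGFA
SHH
TP53
PALB2
MSLN
SMAD4
ATM
STAT3
NFKB1
MSH2
MTHFR
S100P
CLPTM1L
S100A4
PRSS1
IL6
MET
SSTR2
TGFB1
BIRC5
EGFR
TFF2
CTNNB1
MAP2K4
KLF5
GLI1
CXCR4
TERT
ITGB1
CD44
TNF
ERBB2
MMP9
MMP2
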