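# Synthetic stand-in druggable-cancer gene panel (138 genes).
# The original study's DrugBank/OncoKB-derived list is not published;
# this panel is a plausible substitute assembled from well-known
# actionable cancer genes and is intended for examples and simulations.
ABL1
AKT1
AKT2
AKT3
ALK
AR
ARAF
ATM
ATR
AURKA
AURKB
AXL
BCL2
BCL2L1
BRAF
BRCA1
BRCA2
BTK
CCND1
CCND2
CCND3
CCNE1
CDK4
CDK6
CDK7
CDK9
CDK12
CDKN2A
CHEK1
CHEK2
CSF1R
DDR1
DDR2
EGFR
EPHA2
ERBB2
ERBB3
ERBB4
ESR1
EZH2
FGFR1
FGFR2
FGFR3
FGFR4
FLT1
FLT3
FLT4
GNA11
GNAQ
HDAC1
HDAC2
HDAC6
HRAS
IDH1
IDH2
IGF1R
JAK1
JAK2
JAK3
KDR
KIT
KRAS
MAP2K1
MAP2K2
MAPK1
MCL1
MDM2
MDM4
MET
MTOR
NF1
NF2
NRAS
NTRK1
NTRK2
NTRK3
PALB2
PARP1
PARP2
PDGFRA
PDGFRB
PIK3CA
PIK3CB
PIK3CD
PIK3R1
PLK1
PPARG
PTCH1
PTEN
RAF1
RARA
RET
ROS1
SMO
SRC
STK11
SYK
TSC1
TSC2
TP53
VEGFA
WEE1
XPO1
BRD4
ERCC1
TOP1
TOP2A
TYMS
DHFR
RRM1
RRM2
TUBB3
ABCB1
MGMT
PSMB5
PSMD1
HSP90AA1
PTK2
ROCK1
ROCK2
PIM1
PIM2
BCL6
MYC
MYCN
TERT
KMT2A
DOT1L
PRMT5
BCL2L2
CDK2
CDK5
GSK3B
MAP3K1
MAPK3
MERTK
TACC3
TYK2
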