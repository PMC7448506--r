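ATF2
MEF2C
NFE2L1
NF1
USF1
RFX1
BACH1
CUX1
POU2F1
CREB1
NFYA
HNF1A
TCF3
ARNT
STAT3
FOXO1
PML
ACLY
HNF4A
LSS
LAMC1
APP
CDKN1A
MTA3
PTEN
E2F4
SCAP
PCM1
HDAC10
LPIN1
WT1
KRAS
SIRT1
RRP1B
MLXIPL
SLC2A1
ATM
PPP3CA
ITGAV
PNPLA2
VEGFA
TOPBP1
E2F3
IDH2
ABCA1
ALG2
IQCB1
MBNL2
EIF2B3
ACOT8
SLC25A10
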