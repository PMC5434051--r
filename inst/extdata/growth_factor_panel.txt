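# Curated growth-factor receptor panel: receptor tyrosine kinases of the
# EGFR/ERBB, FGFR, PDGFR, IGF, VEGFR, TRK and EPH families, their principal
# ligands, and closely related genes (including BRCA1, an EGFR regulator).
# Reconstruction recipe: search a protein database for human epithelial /
# growth factor receptors, keep reviewed entries with an HGNC symbol, add
# the cognate ligands, and intersect with the genes measured on your
# expression platform. Substitute any panel via a plain-text file, one
# symbol per line.
EGFR
ERBB2
ERBB3
ERBB4
TGFA
EREG
AREG
BTC
HBEGF
EPGN
NRG1
NRG2
NRG3
NRG4
FGFR1
FGFR2
FGFR3
FGFR4
FGF1
FGF2
FGF7
FGF10
PDGFRA
PDGFRB
PDGFA
PDGFB
PDGFC
PDGFD
IGF1R
IGF2R
IGF1
IGF2
INSR
IRS1
KDR
FLT1
FLT4
VEGFA
VEGFB
VEGFC
KIT
KITLG
FLT3
FLT3LG
MET
MST1R
HGF
NTRK1
NTRK2
NTRK3
NGF
BDNF
NTF3
EPHA1
EPHA2
EPHB2
EPHB4
EFNA1
EFNB1
EFNB2
AXL
GAS6
MERTK
TYRO3
RET
GDNF
DDR1
DDR2
ROR1
ROR2
TEK
TIE1
ANGPT1
ANGPT2
TGFB1
TGFBR1
TGFBR2
GRB2
SOS1
SHC1
BRCA1
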