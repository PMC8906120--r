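ligand,receptor,family,mode
VEGFA,KDR,VEGF,secreted
VEGFA,FLT1,VEGF,secreted
VEGFA,NRP1,VEGF,secreted
VEGFB,FLT1,VEGF,secreted
VEGFC,FLT4,VEGF,secreted
PGF,FLT1,VEGF,secreted
TGFB1,TGFBR1,TGFB,secreted
TGFB1,TGFBR2,TGFB,secreted
TGFB2,TGFBR2,TGFB,secreted
TGFB3,TGFBR2,TGFB,secreted
BMP2,BMPR1A,BMP,secreted
BMP4,BMPR1A,BMP,secreted
BMP7,BMPR2,BMP,secreted
PDGFA,PDGFRA,PDGF,secreted
PDGFB,PDGFRB,PDGF,secreted
PDGFC,PDGFRA,PDGF,secreted
PDGFD,PDGFRB,PDGF,secreted
EGF,EGFR,EGF,secreted
TGFA,EGFR,EGF,secreted
HBEGF,EGFR,EGF,secreted
AREG,EGFR,EGF,secreted
NRG1,ERBB3,EGF,secreted
FGF1,FGFR1,FGF,secreted
FGF2,FGFR1,FGF,secreted
FGF7,FGFR2,FGF,secreted
FGF10,FGFR2,FGF,secreted
IGF1,IGF1R,IGF,secreted
IGF2,IGF1R,IGF,secreted
HGF,MET,HGF,secreted
ANGPT1,TEK,ANGPT,secreted
ANGPT2,TEK,ANGPT,secreted
CSF1,CSF1R,CSF,secreted
CSF2,CSF2RA,CSF,secreted
IL34,CSF1R,CSF,secreted
CCL2,CCR2,CC,secreted
CCL3,CCR1,CC,secreted
CCL5,CCR5,CC,secreted
CCL19,CCR7,CC,secreted
CXCL12,CXCR4,CXC,secreted
CXCL8,CXCR2,CXC,secreted
WNT3A,FZD1,WNT,secreted
WNT5A,FZD2,WNT,secreted
DLL1,NOTCH1,NOTCH,contact
DLL4,NOTCH1,NOTCH,contact
JAG1,NOTCH2,NOTCH,contact
EFNB2,EPHB4,EPH,contact
SEMA3A,NRP1,SEMA,secreted
NGF,NTRK1,NT,secreted
BDNF,NTRK2,NT,secreted
KITLG,KIT,unassigned,secreted
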