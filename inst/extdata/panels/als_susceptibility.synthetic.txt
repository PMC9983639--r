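# ALS susceptibility panel (synthetic reconstruction)
# Curated stand-in for a 48-gene GWAS-derived susceptibility panel; assembled from
# public association studies, not the original table.
C9ORF72
SOD1
TBK1
KIF5A
NEK1
UNC13A
MOBP
SCFD1
C21ORF2
TNIP1
GPX3
ACSL5
ERGIC1
COG3
PTPRN2
SPATA2
CAMTA1
KANK1
DPP6
ITPR2
FGGY
ZNF512B
SARM1
MYO18B
SLC9A8
DIP2B
BNIP1
PFKP
CNTN4
CRYZ
SUSD2
RAPGEF5
GGNBP2
ELP3
EPHA4
CX3CR1
CHGB
HFE
PON1
PON2
PON3
VEGFA
SCN7A
NT5C1A
NEFH
DAO
ARPP21
CHRNA4
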