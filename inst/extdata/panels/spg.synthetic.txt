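# Hereditary spastic paraplegia (SPG) panel (synthetic reconstruction)
# Curated 57-gene stand-in assembled from public sources.
SPAST
ATL1
SPG7
PLP1
L1CAM
CYP7B1
SPG11
ZFYVE26
REEP1
KIF5A
WASHC5
KIF1A
RTN2
HSPD1
BSCL2
NIPA1
SLC33A1
ZFYVE27
SPART
SPG21
B4GALNT1
DDHD1
KIF1C
GJC2
GBA2
AP4B1
AP4M1
AP4E1
AP4S1
TECPR2
DDHD2
C12ORF65
CYP2U1
TFG
ERLIN1
ERLIN2
AMPD2
ENTPD1
ARL6IP1
PGAP1
USP8
WDR48
ARSI
PNPLA6
C19ORF12
MARS1
ZFR
RAB3GAP2
MAG
FARS2
CAPN1
ATP13A2
VPS37A
UCHL1
CPT1C
SELENOI
ALDH18A1
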