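# Hereditary motor neuropathies (HMN) panel (synthetic reconstruction)
# Curated 36-gene stand-in assembled from public sources.
IGHMBP2
DNAJB2
BICD2
DYNC1H1
TRPV4
GARS1
HSPB1
HSPB3
HSPB8
SLC5A7
DCTN1
REEP1
AARS1
WARS1
FBXO38
EMILIN1
SORD
VRK1
SCO2
TFG
BSCL2
MORC2
HINT1
MME
DGAT2
DNM2
MFN2
PLEKHG5
ATP7A
LAS1L
SYT2
SLC25A21
VWA1
COQ7
GBF1
SPTAN1
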