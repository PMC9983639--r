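# Spinocerebellar ataxia (SA) panel (synthetic reconstruction)
# Curated 15-gene stand-in assembled from public sources.
ATXN1
ATXN2
ATXN3
CACNA1A
ATXN7
ATXN8OS
ATXN10
PPP2R2B
KCNC3
PRKCG
ITPR1
TGM6
ELOVL5
CCDC88C
SPTBN2
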