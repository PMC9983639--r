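# Spinal muscular atrophy (SMA) panel (synthetic reconstruction)
# Curated 20-gene stand-in assembled from public sources.
SMN1
UBA1
ASAH1
EXOSC3
EXOSC8
EXOSC9
ASCC1
TRIP4
TBCE
ERBB3
GLE1
CNTNAP1
ADCY6
LGI4
ECEL1
IGHMBP2
DNAJB2
BICD2
DYNC1H1
TRPV4
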