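# Small bundled inflammation gene list for tests and examples only.
# Real analyses should supply a curated, analysis-specific list
# (one human gene symbol per line).
IL1B
IL6
IL10
IL18
TNF
NLRP3
CASP1
HMOX1
PTGS2
NAMPT
B2M
ISG15
LTA4H
CXCL2
GSTP1
HSP90AA1
CD14
TLR4
NFKB1
CCL2
TNFAIP3
NR4A2
PLAUR
TANK
ZFP36
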