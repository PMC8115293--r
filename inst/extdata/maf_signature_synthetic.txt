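# Synthetic placeholder gene list for a melanoma-associated-fibroblast
# (MAF) signature. NOT the published signature: a stand-in assembled from
# common fibroblast/CAF marker symbols so that signature-scoring examples
# run without external downloads. Replace with the published gene list for
# real analyses. Lines starting with '#' are comments.
FAP
PDGFRB
ACTA2
PDPN
COL1A1
COL1A2
COL3A1
COL5A1
COL6A3
POSTN
FN1
THY1
DCN
LUM
FBLN1
MMP2
SPARC
TAGLN
VIM
TNC
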