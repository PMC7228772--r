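# Curated list of literature-reported autoantigen gene symbols for
# autoimmune polyendocrine syndrome type 1 (standard HGNC symbols).
# One symbol per line; '#' starts a comment.
AIRE
ASGR1
BPIFA1
BPIFB1
CYP11A1
CYP17A1
CYP1A2
CYP21A2
CYP2A6
DDC
GAD1
GAD2
GIF
IL17A
IL17F
IL22
INS
KCNRG
LCN1
MAGEB2
NLRP5
PDILT
SOX10
TG
TPH1
TPO
TSGA10
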