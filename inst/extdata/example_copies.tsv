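gene_id	copies
EGFR	2
INSR	2
IGF1R	2
KRAS	2
NRAS	2
HRAS	2
RAF1	2
BRAF	2
MAP2K1	2
MAP2K2	2
MAPK1	2
MAPK3	2
PIK3CA	2
PTEN	2
AKT1	2
AKT2	2
MTOR	2
EIF4E	2
EIF4EBP1	2
FOXO3	2
FOS	2
JUN	2
MYC	2
BCL2	2
BAD	2
BCL2L11	2
BBC3	2
PMAIP1	2
BAX	2
BID	2
CASP8	2
CASP3	2
PARP1	2
TNFRSF10B	2
BRCA2	2
MSH6	2
MGMT	2
CCND1	2
CDKN2A	0
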