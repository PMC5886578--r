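gene_id	t_half_mrna_h	t_half_protein_h
EGFR	6	12
INSR	9	24
IGF1R	9	24
KRAS	9	40
NRAS	9	40
HRAS	9	40
RAF1	8	36
BRAF	8	30
MAP2K1	9	46
MAP2K2	9	46
MAPK1	9	60
MAPK3	9	60
PIK3CA	9	30
PTEN	9	30
AKT1	9	36
AKT2	9	36
MTOR	9	40
EIF4E	9	40
EIF4EBP1	9	30
FOXO3	6	8
FOS	0.5	2
JUN	1	3
MYC	0.75	1
BCL2	9	24
BAD	9	12
BCL2L11	4	3
BBC3	3	2.5
PMAIP1	3	2
BAX	9	48
BID	9	40
CASP8	9	40
CASP3	9	40
PARP1	9	60
TNFRSF10B	9	20
BRCA2	6	20
MSH6	9	30
MGMT	9	40
CCND1	1	0.5
CDKN2A	9	24
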