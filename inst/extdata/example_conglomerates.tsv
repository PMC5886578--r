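gene_id	conglomerate_id
EGFR	EGFR
INSR	INSR
IGF1R	INSR
KRAS	RAS
NRAS	RAS
HRAS	RAS
RAF1	CRAF
BRAF	BRAF
MAP2K1	MEK
MAP2K2	MEK
MAPK1	ERK
MAPK3	ERK
PIK3CA	PI3K
PTEN	PTEN
AKT1	AKT
AKT2	AKT
MTOR	MTOR
EIF4E	EIF4E
EIF4EBP1	EIF4EBP1
FOXO3	FOXO
FOS	CFOS
JUN	CJUN
MYC	CMYC
BCL2	BCL2
BAD	BAD
BCL2L11	BIM
BBC3	PUMA
PMAIP1	NOXA
BAX	BAX
BID	BID
CASP8	CASP8
CASP3	CASP3
PARP1	PARP
TNFRSF10B	DR
BRCA2	BRCA2
MSH6	MSH6
MGMT	MGMT
CCND1	CCND1
CDKN2A	CDKN2A
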