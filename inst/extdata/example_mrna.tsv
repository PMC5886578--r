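gene_id	rep1	rep2	rep3
EGFR	185.567731672107	123.451999204877	151.833342489678
INSR	72.7801059671912	74.3839301983252	48.9145462626109
IGF1R	22.1858991135917	16.5902519682453	18.2965965601644
KRAS	69.4133901289233	137.36670877733	86.8821185457657
NRAS	46.0438166246749	47.4779104012597	76.4237449174004
HRAS	34.8113996869918	34.2727950446738	56.7243838030942
RAF1	11.6245616713668	12.8961947007626	12.9274775214989
BRAF	4.71562422714693	6.01519200508523	4.89431123265586
MAP2K1	133.048200541919	106.18076417308	103.669999878362
MAP2K2	174.194997729163	135.763862587346	250.951452609038
MAPK1	277.80208276491	321.757341150395	401.958956112923
MAPK3	42.6731829008363	40.9988490684036	40.6553765052242
PIK3CA	78.0944480837773	71.2208393036187	77.9323209074015
PTEN	85.8206508625442	81.5246440498029	99.4652190993584
AKT1	79.1240030822624	54.7116247240383	96.5642696812263
AKT2	97.0608175710758	82.052475454393	110.658131313424
MTOR	61.1653768665707	41.4717305241058	102.802757348165
EIF4E	118.934455780071	107.408056874999	123.670274138068
EIF4EBP1	75.3369815479384	82.7878773020888	87.6059415133252
FOXO3	35.0702753259621	23.1051179169853	27.3075880392698
FOS	0	0	0
JUN	21.7191065651456	29.2692002621784	28.3517483001722
MYC	61.6997840730385	75.9838635882175	66.8698465025064
BCL2	35.2890933336222	42.7202141146927	64.8890991970572
BAD	22.3888141208962	18.8134733920594	16.5379216680081
BCL2L11	13.7618160032151	10.7420549810303	7.87608005652063
BBC3	3.61534486843602	6.59596158559018	6.82016408006227
PMAIP1	4.28469961763039	4.94478557992534	5.22813181098879
BAX	66.0563405587173	53.5726924484369	62.4778364612954
BID	32.7678605262829	39.2620153595662	30.3163958114251
CASP8	25.0698161707988	36.6259115017021	33.6142701171559
CASP3	55.2150152139675	71.0263823476823	56.2023898817311
PARP1	92.2915938402084	133.797279998202	112.605544450298
TNFRSF10B	19.9012329294625	17.6783746898336	26.0879739637852
BRCA2	8.43457238603674	6.87477598025846	7.87107420948992
MSH6	28.8452785449989	27.1432200583789	31.1866476792615
MGMT	23.86439450367	20.7505983306899	19.9386231469291
CCND1	14.9238041463848	15.533335158054	14.1415508438247
CDKN2A	0	0	0
BG0001	128.652269040014	120.60433614787	142.328575668366
BG0002	216.948827404188	219.852999423675	181.353275536182
BG0003	1343.75139496399	785.160362019526	1173.08790951137
BG0004	9557.66594279329	10877.0787436556	8948.71075702926
BG0005	86.2371144714564	71.9399636423679	84.2436754425181
BG0006	9334.98890415479	9293.8072308358	8860.20713181748
BG0007	6801.53006701013	15354.9155808789	9453.07808112437
BG0008	1324.93607515614	2456.87204682555	1860.06960468945
BG0009	1282.8168186683	1155.06028092326	1229.51205006037
BG0010	29.0418943495687	38.3762820176102	34.6230428130311
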