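gene_id	rep1	rep2	rep3
EGFR	218.522945604319	148.524407047855	115.138228145696
INSR	25.8274142620365	25.2898656188141	33.3169552303636
IGF1R	13.9182232520179	13.5912412804491	19.7662255961155
KRAS	22.8986228565093	22.7541299759296	37.499111215345
NRAS	23.1656667257597	18.3878050754283	19.9550579784704
HRAS	20.6371207472206	13.9542917218848	18.0704240339831
RAF1	30.3357880809795	27.7741754588644	33.8969284990724
BRAF	2.58648655372227	4.59329000922417	2.84862832773294
MAP2K1	105.793009703139	151.544964928321	148.209646068683
MAP2K2	507.196371361501	281.746879554132	513.478321249666
MAPK1	856.016579012916	897.286739509073	463.626240730054
MAPK3	75.6971974567298	72.0828508245503	78.8852817590404
PIK3CA	50.7743120722067	52.878386180552	36.9307064854296
PTEN	77.595180857258	60.6423137125605	42.4613323641506
AKT1	68.2222841559237	102.772474657427	65.1635012870577
AKT2	63.9149675616948	81.1985021759484	79.2532721294748
MTOR	36.3053404124979	26.9432270412723	27.3973673286739
EIF4E	229.431025879689	295.947482580555	243.031302935962
EIF4EBP1	135.821060561041	114.444196776014	171.86940910551
FOXO3	37.3507022428084	21.7557846683544	16.0512341331249
FOS	0	0	0
JUN	2.99516884151607	3.79950587735085	3.50125141680893
MYC	60.1431548646885	52.3802507596414	37.9055406461366
BCL2	81.8133980462516	56.0304021687193	58.0848304548627
BAD	16.9847489781922	12.9910916819303	19.4264079426186
BCL2L11	8.23852365838223	9.53950556593061	8.83803590635193
BBC3	2.92275878056596	2.02460491566083	2.9937288073604
PMAIP1	2.23350431160228	1.71465978064014	2.83191393829247
BAX	99.4589444190858	108.412587110652	102.547784931858
BID	25.2165248310909	34.8057580674942	31.6225370898571
CASP8	38.1705743908032	21.360734060117	37.1547097228862
CASP3	46.6401015661951	51.9404332034746	50.0928575100855
PARP1	188.672952438205	158.89524677631	215.812330357802
TNFRSF10B	10.5140984051441	8.80637536063526	8.99828476360885
BRCA2	2.00455936188772	2.59364837930283	1.69935374056261
MSH6	13.5236995709822	24.3877139213955	19.8160580592836
MGMT	9.19035358404283	9.62398493881157	8.94527119282526
CCND1	5.64460182234209	4.15631773168383	5.84318215146772
CDKN2A	0	0	0
BG0001	1301.79113733056	2290.97892619249	1434.67069034518
BG0002	6.29288981984471	8.56525280715183	5.98776270844045
BG0003	30989.2454377366	54430.9785000426	62865.0050156959
BG0004	31945.3723208334	26619.9235332569	24304.3354601276
BG0005	44501.9241848042	54835.8019078294	39528.6269129678
BG0006	4129.92748461595	4234.2066989518	3444.72184659815
BG0007	54.0504985693785	70.9322134177927	54.9190904601022
BG0008	7127.41933667443	5933.83888834972	9511.86646676503
BG0009	1.17284008077396	0.56737958278341	1.10714102592905
BG0010	40818.5331659802	38214.337097906	37017.985174301
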