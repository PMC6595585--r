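gene_id	mat_total	pat_total
MEG3	5002	23
PHLDA2	154	5
RTL1	687	35
H19	20522	1393
PEG10	13	6101
IGF2	52	6695
MEST	10	850
ZFAT	138	9652
PLAGL1	10	402
DLK1	50	1467
AIM1	65	971
KLHDC10	248	83
NLRP2	697	282
GRB10	302	146
NAA60	164	82
CPXM2	72	588
MCCC1	14	101
PLEKHG4B	52	292
DCAF10	15	78
DNMT1	71	353
NUDT12	5	24
RHOBTB3	2264	10119
ZDBF2	226	878
MKRN3	44	102
GRHL1	1825	3399
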