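gene	count	length
AHNAK	762	113317
ARS2	105	13551
BPGM	102	33014
C14orf138	22	7942
CCM2	373	76283
CNOT4	309	148303
COMMD6	18	11871
DIP2A	471	109711
DKFZp761I2123	161	20951
DNAJA5	76	29372
EGFR	695	188307
ERCC1	118	14306
FLJ20097	232	126686
FMO3	57	26924
FOXM1	86	19455
FPRL1	41	9327
FUS	82	11648
GMFB	24	14536
HTF9C	69	5371
IFRD1	171	53022
IMPDH1	176	17976
ITM2C	135	14343
KIAA2010	174	52859
KRIT1	105	47132
LOC285989	86	14703
MAWBP	204	50268
MGC3207	72	9751
MGC4707	815	227682
NGFRAP1	19	1734
NT5C3	120	48668
PHF14	336	195730
PLEKHH1	295	56220
PPP1R9A	742	386048
RAB37	457	76205
RAP1B	130	49723
RGS6	2135	630822
SEMA5B	786	119412
SF1	78	14164
SLC37A3	303	64760
SP8	29	4605
SUNC1	109	41972
SYNJ1	256	99205
TFEC	145	95597
TJP2	283	81032
TRAF7	273	22332
UPP1	108	19976
USP42	26	56635
ZAP70	222	26293
ZCCHC11	312	129797
ZNF32	25	5020
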