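gene	alp_z	mdd_z
NR4A1	6.02	-2.72
FOS	5.48	-2.95
EGR4	4.78	-4.53
BDNF	4.78	-3.82
JUNB	4.45	-2.27
RPS13	4.40	2.06
IER2	4.29	-2.16
HOMER1	4.10	-2.71
DUSP6	3.94	-4.97
NR4A2	3.91	-3.93
FOSL2	3.74	-4.11
CREM	3.68	-3.21
SIK1	3.59	-2.96
SRF	3.54	-2.19
RGS2	3.37	-2.48
TXNIP	-5.45	2.24
ETS2	-5.05	-4.04
KLF11	-4.95	2.51
NR4A3	-4.92	-2.46
GSE1	-4.87	-2.82
BCL2L11	-4.69	2.93
IER5	-4.60	-2.15
FBXL3	-4.44	2.01
KLF15	-4.29	2.70
CREBRF	-4.24	2.44
PLXNA2	-4.20	-4.06
PIK3IP1	-4.16	3.38
ZKSCAN1	-4.14	3.95
DSTYK	-4.06	3.90
ZEB2	-4.01	2.72
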