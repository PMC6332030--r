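# descriptor: polarizability
# units: 1e-24 cm3
backbone	neighbors	contribution	occurrences	molecules
Const		0.62	406	406
C sp3	H3C	1.92	351	219
C sp3	H3N	4.67	16	12
C sp3	H3O	3.50	32	23
C sp3	H3S	3.42	6	3
C sp3	H2C2	1.80	410	123
C sp3	H2CN	4.52	25	16
C sp3	H2CN(+)	4.56	2	2
C sp3	H2CO	3.35	78	51
C sp3	H2CS	3.14	3	2
C sp3	H2CF	2.19	11	11
C sp3	H2CCl	3.90	19	17
C sp3	H2CBr	4.86	15	14
C sp3	H2CJ	7.26	3	3
C sp3	H2O2	5.49	1	1
C sp3	H2OCl	5.69	1	1
C sp3	HC3	1.80	16	13
C sp3	HC2N	4.43	1	1
C sp3	HC2O	3.13	5	4
C sp3	HC2Cl	3.72	12	12
C sp3	HC2Br	5.13	1	1
C sp3	HCNCl(+)	7.56	2	2
C sp3	HCO2	6.37	5	3
C sp3	HCF2	2.07	1	1
C sp3	HCCl2	5.71	4	4
C sp3	C4	1.47	13	10
C sp3	C3N(+)	4.26	1	1
C sp3	C3Cl	6.11	1	1
C sp3	CF3	2.65	4	3
C sp3	CF2Cl	4.02	5	4
C sp3	CCl3	7.90	3	3
C sp3	O4	9.21	1	1
C sp2	H2=C	1.96	39	31
C sp2	HC=C	1.95	70	40
C sp2	HC=N	2.38	4	4
C sp2	HC=O	2.05	8	8
C sp2	H=CN	2.32	13	9
C sp2	H=CO	1.65	2	1
C sp2	H=CS	3.15	4	2
C sp2	H=CCl	3.80	10	8
C sp2	H=CBr	4.88	4	4
C sp2	H=CJ	6.72	1	1
C sp2	HN=N	4.11	6	5
C sp2	HN=O	4.32	3	3
C sp2	HO=O	3.17	4	4
C sp2	C2=C	1.83	18	14
C sp2	C2=N	3.64	2	1
C sp2	C2=O	2.48	19	14
C sp2	C=CN	2.13	4	4
C sp2	C=CO	1.82	3	3
C sp2	C=CCl	4.46	2	1
C sp2	CN=N	4.66	2	2
C sp2	CN=O	3.88	8	8
C sp2	CO=O	2.63	33	31
C sp2	C=OCl	4.07	1	1
C sp2	=CN2	3.55	2	2
C sp2	=CF2	0.20	1	1
C sp2	=CCl2	5.43	2	2
C sp2	N2=N	4.20	1	1
C sp2	N2=O	3.46	3	3
C sp2	O2=O	3.47	2	2
C sp2	O=OCl	4.72	2	2
C aromatic	H:C2	1.68	777	130
C aromatic	H:C:N	2.51	17	9
C aromatic	H:N2	2.86	1	1
C aromatic	:C3	1.91	125	40
C aromatic	C:C2	1.52	116	52
C aromatic	C:C:N	2.22	4	3
C aromatic	:C2N	3.59	27	24
C aromatic	:C2N(+)	3.94	11	8
C aromatic	:C2:N	2.35	17	8
C aromatic	:C2O	2.50	21	12
C aromatic	:C2S	3.45	6	3
C aromatic	:C2F	1.51	42	15
C aromatic	:C2Cl	3.47	18	12
C aromatic	:C2Br	4.49	10	9
C aromatic	:C2J	6.48	5	5
C sp	H#C	1.46	12	10
C sp	C#C	1.59	12	9
C sp	C#N	1.92	22	19
C sp	#CCl	3.99	1	1
C sp	#CBr	5.31	1	1
C sp	=C=O	1.82	1	1
N sp3	H2C	-1.13	7	6
N sp3	H2C(pi)	-0.53	25	22
N sp3	H2N	1.41	5	4
N sp3	HC2	-3.29	3	3
N sp3	HC2(pi)	-3.78	5	5
N sp3	HC2(2pi)	-1.24	11	7
N sp3	HCN(pi)	-1.12	1	1
N sp3	HCN(2pi)	-0.04	1	1
N sp3	C3	-6.73	3	3
N sp3	C3(pi)	-6.73	4	4
N sp3	C3(2pi)	-4.26	2	2
N sp3	C2N(pi)	-3.87	2	2
N sp3	C2N(2pi)	-2.95	3	3
N sp2	H=C	-1.73	1	1
N sp2	C=C	-0.94	8	6
N sp2	=CN	0.00	6	5
N sp2	O=O	1.11	1	1
N aromatic	:C2	-0.82	19	13
N aromatic	:C:N	0.14	2	1
N(+) sp2	CO=O(-)	-0.35	16	13
O	HC	-0.77	19	18
O	HC(pi)	-0.04	13	13
O	HS	2.38	2	1
O	C2	-2.71	31	21
O	C2(pi)	-1.68	34	31
O	C2(2pi)	-0.61	11	10
O	CN(pi)	0.00	1	1
O	CS	0.56	4	2
O	CP	-0.04	12	4
P3	O3	-0.61	1	1
P4	O3=O	-0.60	2	2
P4	O3=S	1.81	1	1
S2	HC	1.70	1	1
S2	C2	0.06	2	2
S2	C2(2pi)	-0.54	3	3
S4	C2=O	0.25	2	2
S4	C2=O2	0.08	2	2
S4	O2=O2	0.00	3	3
#stat	A	based_on		406
#stat	B	R2	0.995	351
#stat	C	MAE	0.35	351
#stat	D	SD	0.51	351
#stat	E	k	10	308
#stat	F	Q2	0.9897	308
#stat	G	MAE_cv	0.46	308
#stat	H	SD_cv	0.76	308
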