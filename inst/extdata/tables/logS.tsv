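# descriptor: logS
# units: log10 mol/L
backbone	neighbors	contribution	occurrences	molecules
Const		0.44	1492	1492
C sp3	H3C	-0.31	1571	806
C sp3	H3N	-0.87	173	113
C sp3	H3N(+)	-0.03	2	2
C sp3	H3O	-0.32	157	110
C sp3	H3S	-0.15	12	10
C sp3	H2C2	-0.32	2091	604
C sp3	H2CN	-0.85	278	144
C sp3	H2CN(+)	-0.68	6	5
C sp3	H2CO	-0.29	328	248
C sp3	H2CS	-0.10	43	30
C sp3	H2CP	-5.15	1	1
C sp3	H2CF	-0.83	1	1
C sp3	H2CCl	-0.62	41	34
C sp3	H2CBr	-1.29	18	16
C sp3	H2CJ	-1.75	5	5
C sp3	H2N2	-1.58	2	2
C sp3	H2NO	-0.99	9	9
C sp3	H2NS	-1.11	2	2
C sp3	H2O2	-0.67	6	6
C sp3	H2S2	-0.47	5	5
C sp3	H2SCl	-1.06	1	1
C sp3	HC3	-0.26	531	270
C sp3	HC2N	-0.81	72	60
C sp3	HC2N(+)	-0.71	23	22
C sp3	HC2O	-0.38	321	174
C sp3	HC2S	-0.46	8	6
C sp3	HC2F	-1.85	1	1
C sp3	HC2Cl	-0.89	28	16
C sp3	HC2Br	-1.02	4	4
C sp3	HC2J	-1.90	1	1
C sp3	HCO2	-0.69	28	17
C sp3	HCOBr	-4.65	1	1
C sp3	HCCl2	-1.24	13	12
C sp3	HCClBr	-1.05	1	1
C sp3	HOF2	-0.36	1	1
C sp3	C4	-0.17	234	162
C sp3	C3N	-0.64	16	16
C sp3	C3O	-0.15	91	82
C sp3	C3S	0.18	2	2
C sp3	C3F	-0.52	10	10
C sp3	C3Cl	-0.42	34	12
C sp3	C3Br	-0.69	1	1
C sp3	C2O2	-1.35	8	8
C sp3	C2Cl2	-2.25	11	10
C sp3	CF3	-1.09	24	24
C sp3	CF2Cl	-1.78	3	2
C sp3	CFCl2	-1.70	1	1
C sp3	CCl3	-2.12	12	11
C sp3	CCl2Br	0.00	1	1
C sp2	H2=C	-0.53	74	63
C sp2	HC=C	-0.27	338	204
C sp2	HC=N	-2.17	9	9
C sp2	HC=O	0.24	22	22
C sp2	H=CN	-0.54	23	21
C sp2	H=CO	-0.13	8	7
C sp2	H=CS	-0.32	9	6
C sp2	H=CCl	-1.00	6	5
C sp2	H=CBr	-0.88	2	1
C sp2	H=CJ	-1.83	2	1
C sp2	HN=N	-1.95	19	12
C sp2	HN=O	-0.19	2	2
C sp2	H=NO	-0.65	1	1
C sp2	HO=O	-0.22	7	7
C sp2	H=NS	-0.25	1	1
C sp2	C2=C	-0.26	153	128
C sp2	C2=N	-0.84	11	10
C sp2	C2=O	0.01	188	132
C sp2	C=CN	-1.05	25	22
C sp2	C=CO	-0.35	44	32
C sp2	C=CS	-0.14	5	5
C sp2	C=CF	-0.62	2	2
C sp2	C=CCl	-0.91	45	25
C sp2	C=CBr	-0.45	3	3
C sp2	CN=N	-1.67	9	8
C sp2	CN=O	-0.33	261	201
C sp2	C=NO	-1.87	5	5
C sp2	=CNO(+)	-1.68	2	2
C sp2	C=NS	-0.34	2	2
C sp2	CO=O	-0.06	306	266
C sp2	CO=O(-)	0.50	23	23
C sp2	C=OS	2.17	1	1
C sp2	=CCl2	-1.66	14	11
C sp2	=CBr2	-3.04	1	1
C sp2	N2=O	-1.46	98	95
C sp2	N2=S	-1.93	10	10
C sp2	NO=O	-0.55	48	45
C sp2	N=OS	-0.83	7	7
C sp2	=NS2	-1.09	1	1
C aromatic	H:C2	-0.30	4203	812
C aromatic	H:C:N	0.51	91	60
C aromatic	H:N2	0.37	7	7
C aromatic	:C3	-0.36	281	87
C aromatic	C:C2	-0.39	927	556
C aromatic	C:C:N	0.65	27	23
C aromatic	:C2N	-0.74	270	216
C aromatic	:C2N(+)	-0.72	68	50
C aromatic	:C2:N	-0.31	29	22
C aromatic	:C2O	-0.25	376	252
C aromatic	:C2S	-0.23	42	26
C aromatic	:C2F	-0.61	36	19
C aromatic	:C2Cl	-1.10	570	215
C aromatic	:C2Br	-1.53	38	24
C aromatic	:C2J	-1.47	21	16
C aromatic	:CN:N	-0.91	34	24
C aromatic	C:N2	0.10	2	2
C aromatic	:C:NO	0.13	12	12
C aromatic	:C:NCl	-0.87	5	5
C aromatic	N:N2	-0.94	24	15
C aromatic	:N2Cl	-0.54	7	7
C sp	H#C	-0.21	17	16
C sp	C#C	-0.55	19	17
C sp	C#N	-0.19	26	24
C sp	=N=S	-2.99	1	1
N sp3	H2C	0.93	12	9
N sp3	H2C(pi)	0.60	111	99
N sp3	H2N	0.61	4	4
N sp3	HC2	2.25	20	17
N sp3	HC2(pi)	1.29	75	66
N sp3	HC2(2pi)	0.74	211	158
N sp3	HCN	0.76	2	2
N sp3	HCN(pi)	0.34	7	6
N sp3	HCN(2pi)	-0.41	3	3
N sp3	C3	3.15	64	57
N sp3	C3(pi)	2.20	66	60
N sp3	C3(2pi)	1.62	80	75
N sp3	C3(3pi)	1.30	7	7
N sp3	C2N	1.44	1	1
N sp3	C2N(pi)	2.80	4	4
N sp3	C2N(2pi)	1.30	17	13
N sp3	C2N(3pi)	0.72	6	6
N sp2	C=C	1.49	35	32
N sp2	C=N	-0.22	3	2
N sp2	=CN	1.83	15	13
N sp2	=CO	1.52	7	7
N sp2	=CS	-0.37	2	1
N sp2	N=N	2.08	1	1
N sp2	N=O	-0.54	4	4
N(+) sp3	H3C	0.50	21	21
N(+) sp3	H2C2	0.29	1	1
N(+) sp3	HC3	1.97	1	1
N(+) sp2	CO=O(-)	-0.15	75	57
N(+) sp2	O2=O(-)	-0.54	5	2
N aromatic	:C2	-0.58	138	89
N aromatic	:C:N	0.11	2	1
O	HC	0.60	377	217
O	HC(pi)	0.34	306	240
O	HN(pi)	1.00	1	1
O	C2	0.69	106	63
O	C2(pi)	0.24	320	249
O	C2(2pi)	-0.25	76	72
O	CN(+)(pi)	-0.21	5	2
O	CN(2pi)	-0.30	6	6
O	CP	-0.07	78	36
O	CP(pi)	-1.23	25	20
P4	CO2=S	5.44	1	1
P4	O3=O	2.79	7	7
P4	O3=S	0.45	16	15
P4	O2=OS	0.67	2	2
P4	O2S=S	-1.43	14	13
S2	HC	-0.54	3	3
S2	HC(pi)	-0.84	2	2
S2	C2	-0.53	14	14
S2	C2(pi)	-1.03	12	12
S2	C2(2pi)	-1.02	25	25
S2	CP	0.21	16	15
S2	CS	-0.84	5	3
S2	N2(2pi)	0.00	1	1
S4	C2=O	0.91	3	3
S4	C2=O2	0.09	6	6
S4	C=OS	1.38	1	1
H	H Acceptor	-0.48	85	68
Alkane	No of C atoms	-0.33	282	39
Unsaturated HC	No of C atoms	-0.10	1350	121
X(CH2)n	No of CH2 groups	-0.12	1220	426
#stat	A	based_on		1492
#stat	B	R2	0.9051	1441
#stat	C	MAE	0.52	1441
#stat	D	SD	0.67	1441
#stat	E	k	10	1419
#stat	F	Q2	0.8838	1419
#stat	G	MAE_cv	0.57	1419
#stat	H	SD_cv	0.74	1419
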