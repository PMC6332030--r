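# descriptor: logP
# units: log10 units
backbone	neighbors	contribution	occurrences	molecules
Const		0.25	2780	2780
C sp3	H3C	0.47	1969	1118
C sp3	H3N	0.39	435	300
C sp3	H3N(+)	-0.31	1	1
C sp3	H3O	-0.09	340	250
C sp3	H3S	-0.19	56	51
C sp3	H2C2	0.35	2064	714
C sp3	H2CN	0.36	701	387
C sp3	H2CN(+)	-0.34	23	19
C sp3	H2CO	-0.24	558	430
C sp3	H2CS	-0.38	76	59
C sp3	H2CF	-0.31	5	5
C sp3	H2CCl	0.48	51	38
C sp3	H2CBr	0.88	22	19
C sp3	H2CJ	0.99	3	3
C sp3	H2CP	2.89	1	1
C sp3	H2N2	1.57	4	4
C sp3	H2NO	0.15	5	5
C sp3	H2NS	0.64	3	3
C sp3	H2O2	-0.06	7	7
C sp3	H2S2	-1.23	4	4
C sp3	HC3	0.21	388	230
C sp3	HC2N	0.32	210	167
C sp3	HC2N(+)	-0.36	27	26
C sp3	HC2O	-0.18	389	193
C sp3	HC2S	-0.64	8	8
C sp3	HC2F	0.21	1	1
C sp3	HC2Cl	0.61	60	18
C sp3	HC2Br	0.71	7	5
C sp3	HCN2	1.00	6	5
C sp3	HCNO	0.64	20	20
C sp3	HCNS	0.52	30	30
C sp3	HCO2	-0.47	41	24
C sp3	HCOS	0.00	3	3
C sp3	HCOCl	0.11	3	1
C sp3	HCOBr	1.25	1	1
C sp3	HCOP	0.44	1	1
C sp3	HCF2	0.35	2	2
C sp3	HCCl2	1.15	10	9
C sp3	HOF2	-0.14	1	1
C sp3	C4	-0.09	131	101
C sp3	C3N	0.33	31	30
C sp3	C3N(+)	-0.78	1	1
C sp3	C3O	-0.23	71	59
C sp3	C3S	-0.46	17	17
C sp3	C3F	0.94	3	3
C sp3	C3Cl	0.56	28	8
C sp3	C3Br	0.70	1	1
C sp3	C2N2	-1.56	1	1
C sp3	C2NO	-0.04	5	5
C sp3	C2O2	0.22	6	6
C sp3	C2F2	0.63	2	2
C sp3	C2Cl2	0.73	11	10
C sp3	CNO2	1.35	1	1
C sp3	CF3	1.06	74	72
C sp3	CF2Cl	1.34	3	2
C sp3	CFCl2	1.34	3	2
C sp3	CCl3	1.71	20	18
C sp3	CCl2Br	0.00	1	1
C sp3	OF3	1.05	2	2
C sp3	SF3	1.24	7	7
C sp3	SFCl2	1.20	1	1
C sp3	SCl3	0.93	3	3
C sp2	H2=C	0.57	74	65
C sp2	H2=N	-0.77	1	1
C sp2	HC=C	0.25	390	249
C sp2	HC=N	-0.64	24	24
C sp2	HC=O	-0.48	32	32
C sp2	H=CN	0.02	104	90
C sp2	H=CN(+)	-0.23	17	17
C sp2	H=CO	0.70	13	12
C sp2	H=CS	-0.37	15	14
C sp2	H=CCl	0.77	10	8
C sp2	H=CBr	0.75	1	1
C sp2	HN=N	0.19	70	54
C sp2	HN=O	-0.38	12	11
C sp2	HO=O	-0.06	5	5
C sp2	H=NS	-0.35	4	4
C sp2	C2=C	0.19	150	126
C sp2	C2=N	-0.06	88	85
C sp2	C2=N(+)	1.59	1	1
C sp2	C2=O	-0.61	209	166
C sp2	C=CN	0.50	86	73
C sp2	C=CN(+)	-0.36	3	3
C sp2	C=CO	0.59	43	38
C sp2	C=CS	-0.15	19	14
C sp2	C=CF	0.02	3	3
C sp2	C=CCl	0.97	30	20
C sp2	C=CBr	0.93	4	4
C sp2	C=CJ	0.95	1	1
C sp2	C=CP	0.00	1	1
C sp2	=CN2	0.98	24	24
C sp2	=CN2(+)	0.65	11	11
C sp2	CN=N	0.32	68	65
C sp2	CN=N(+)	-0.10	2	2
C sp2	CN=O	-0.59	468	376
C sp2	C=NO	-0.60	1	1
C sp2	=CNO	0.61	4	4
C sp2	=CNO(+)	0.03	2	2
C sp2	CN=S	-0.24	8	8
C sp2	C=NS	-0.45	6	5
C sp2	=CNS	-0.52	5	5
C sp2	=CNCl	3.11	1	1
C sp2	=CNBr	1.00	5	3
C sp2	C=NCl	2.40	1	1
C sp2	CO=O	0.14	522	473
C sp2	CO=O(-)	-2.32	43	43
C sp2	C=OS	-1.34	4	4
C sp2	=COCl	1.54	1	1
C sp2	=CSBr	-1.69	1	1
C sp2	=CF2	0.42	1	1
C sp2	=CCl2	1.40	12	10
C sp2	=CBr2	1.48	1	1
C sp2	N2=N	0.77	28	27
C sp2	N2=N(+)	0.92	2	2
C sp2	N2=O	0.10	141	139
C sp2	N=NO	0.20	1	1
C sp2	N2=S	0.33	8	7
C sp2	N=NS	0.15	26	26
C sp2	N=NCl	1.79	3	3
C sp2	N=NBr	0.79	3	2
C sp2	NO=O	0.33	116	113
C sp2	=NOS	-0.06	1	1
C sp2	N=OS	-0.13	7	7
C sp2	NO=S	0.93	1	1
C sp2	=NS2	-1.52	2	2
C sp2	NS=S	-0.79	5	3
C sp2	=NSCl	0.71	1	1
C aromatic	H:C2	0.32	9660	2071
C aromatic	H:C:N	-0.40	277	192
C aromatic	H:C:N(+)	-0.94	24	23
C aromatic	H:N2	-1.08	10	10
C aromatic	:C3	0.16	390	171
C aromatic	C:C2	0.18	1982	1323
C aromatic	C:C:N	-0.49	73	63
C aromatic	C:C:N(+)	-0.45	4	4
C aromatic	:C2N	0.28	639	526
C aromatic	:C2N(+)	0.10	188	154
C aromatic	:C2:N	-0.10	93	72
C aromatic	:C2:N(+)	-0.01	20	20
C aromatic	:C2O	0.62	1096	749
C aromatic	:C2S	-0.15	177	143
C aromatic	:C2F	0.40	103	72
C aromatic	:C2Cl	0.86	1707	556
C aromatic	:C2Br	0.97	242	105
C aromatic	:C2J	1.32	50	34
C aromatic	:C2P	0.62	1	1
C aromatic	C:N2	-1.31	8	8
C aromatic	:C:N2	-1.33	1	1
C aromatic	:CN:N	0.68	36	32
C aromatic	:C:NO	0.57	26	18
C aromatic	:C:NS	-0.07	5	5
C aromatic	:C:NF	0.40	1	1
C aromatic	:C:NCl	0.31	18	16
C aromatic	:C:NBr	0.20	1	1
C aromatic	N:N2	0.36	54	42
C aromatic	:N3	-0.41	4	4
C aromatic	:N2O	0.55	9	9
C aromatic	:N2S	-0.51	3	3
C aromatic	:N2Cl	-0.23	8	7
C sp	H#C	-0.16	10	10
C sp	C#C	0.28	18	14
C sp	C#N	-0.18	90	86
C sp	N#N	0.68	2	2
C sp	#NS	-0.62	3	3
C sp	=N=S	1.86	22	21
N sp3	H2C	-1.37	56	56
N sp3	H2C(pi)	-0.84	313	287
N sp3	H2N	-0.58	17	17
N sp3	H2S	-1.13	36	36
N sp3	HC2	-1.19	64	63
N sp3	HC2(pi)	-0.89	237	213
N sp3	HC2(2pi)	-0.40	328	283
N sp3	HCN	-1.11	4	3
N sp3	HCN(pi)	-0.41	10	9
N sp3	HCN(2pi)	0.77	48	48
N sp3	HCO	-2.22	1	1
N sp3	HCO(pi)	-1.14	8	8
N sp3	HCS	-1.44	4	4
N sp3	HCS(pi)	-1.23	50	50
N sp3	HCP	-2.08	3	3
N sp3	HCP(pi)	-0.68	1	1
N sp3	C3	-1.31	136	120
N sp3	C3(pi)	-0.97	151	136
N sp3	C3(2pi)	-0.73	153	140
N sp3	C3(3pi)	-0.84	23	23
N sp3	C2N	-1.66	1	1
N sp3	C2N(pi)	-1.58	31	28
N sp3	C2N(2pi)	-0.75	54	50
N sp3	C2N(3pi)	-0.91	8	8
N sp3	C2O(pi)	-0.38	5	5
N sp3	C2S	-1.18	7	7
N sp3	C2S(pi)	0.07	7	6
N sp3	C2S(2pi)	0.99	2	2
N sp3	C2P	0.02	2	2
N sp3	CN2(2pi)	2.12	1	1
N sp3	CS2	-0.28	1	1
N sp3	CS2(pi)	-0.55	1	1
N sp2	H=C	-0.77	16	13
N sp2	C=C	-0.71	195	173
N sp2	C=N	-0.15	17	16
N sp2	=CN	0.36	100	81
N sp2	C=N(+)	-6.37	1	1
N sp2	=CN(+)	-0.85	2	2
N sp2	=CO	-0.26	34	29
N sp2	C=O	-0.74	2	2
N sp2	=CS	-1.52	6	5
N sp2	N=N	-0.61	29	22
N sp2	N=O	0.25	40	37
N aromatic	H2:C(+)	0.51	7	4
N aromatic	HC:C(+)	-0.13	4	3
N aromatic	C2:C(+)	-0.55	1	1
N aromatic	:C2	0.43	356	258
N aromatic	:C:N	-0.27	4	2
N(+) sp3	H3C	-0.81	29	29
N(+) sp3	H2C2	0.08	5	5
N(+) sp3	HC3	1.15	1	1
N(+) sp2	C=CO(-)	0.08	1	1
N(+) sp2	CO=O(-)	0.14	233	195
N(+) sp2	NO=O(-)	-0.21	2	2
N(+) sp2	O2=O(-)	0.53	1	1
N(+) aromatic	H:C2	0.92	4	4
N(+) aromatic	:C2O(-)	-0.58	20	20
N(+) sp	=C=N(-)	1.60	1	1
N(+) sp	=N2(-)	0.00	1	1
O	HC	-0.55	424	263
O	HC(pi)	-0.69	587	528
O	HN	-0.06	10	10
O	HN(pi)	0.02	6	6
O	C2	0.30	188	114
O	C2(pi)	-0.29	599	478
O	C2(2pi)	-0.78	298	277
O	CN	0.19	3	3
O	CN(pi)	0.43	7	7
O	CN(+)(pi)	-0.04	1	1
O	CN(2pi)	0.02	14	13
O	CS	0.05	4	2
O	CS(pi)	-1.19	4	4
O	CP	0.34	96	49
O	CP(pi)	-0.70	40	28
O	N2(2pi)	0.80	4	4
S2	HC	0.87	6	6
S2	HC(pi)	0.32	3	3
S2	C2	1.35	47	46
S2	C2(pi)	1.18	63	61
S2	C2(2pi)	1.42	49	48
S2	CN	0.00	3	3
S2	CN(2pi)	2.51	1	1
S2	CS	0.95	2	1
S2	CS(pi)	1.72	4	2
S2	CP	1.11	16	14
S2	CP(pi)	0.63	3	2
S2	N2	-2.67	2	2
S2	N2(2pi)	5.74	1	1
S4	C2=O	-0.71	9	9
S4	C2=O2	-0.22	14	14
S4	CO=O2	-0.36	2	1
S4	CN=O2	0.01	92	86
S4	C=O2F	0.62	2	2
S4	NO=O2	0.00	4	4
S4	N2=O2	1.27	5	5
S4	O2=O	0.71	1	1
P4	CO2=O	-1.84	2	2
P4	CO2=S	0.36	1	1
P4	COS=S	-2.39	1	1
P4	O3=O	-0.95	21	21
P4	O3=S	0.98	12	12
P4	O2=OS	0.43	1	1
P4	O2S=S	0.63	11	10
P4	O=OS2	-0.82	2	2
P4	N2O=O	-0.34	2	2
P4	NO=OS	-1.47	2	2
H	H Acceptor	0.49	151	139
Alkane	No of C atoms	0.16	274	30
Unsaturated HC	No of C atoms	0.05	1473	125
X(CH2)n	No of CH2 groups	0.10	1362	579
#stat	A	based_on		2780
#stat	B	R2	0.9543	2697
#stat	C	MAE	0.35	2697
#stat	D	SD	0.46	2697
#stat	E	k	10	2638
#stat	F	Q2	0.9448	2638
#stat	G	MAE_cv	0.38	2638
#stat	H	SD_cv	0.51	2638
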