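# descriptor: toxicity
# units: -log10 mmol/L
backbone	neighbors	contribution	occurrences	molecules
Const		-1.66	859	859
C sp3	H3C	0.24	772	469
C sp3	H3N	0.13	12	5
C sp3	H3O	0.49	72	67
C sp3	H3S	0.31	5	3
C sp3	H2C2	0.34	986	313
C sp3	H2CN	0.08	10	7
C sp3	H2CN(+)	0.55	4	4
C sp3	H2CO	0.58	205	188
C sp3	H2CS	0.34	31	18
C sp3	H2CCl	0.31	13	13
C sp3	H2CBr	0.75	15	14
C sp3	H2CJ	0.86	2	2
C sp3	HC3	0.14	63	58
C sp3	HC2O	0.45	51	50
C sp3	HC2S	0.00	1	1
C sp3	HC2Cl	-0.07	1	1
C sp3	HC2Br	0.75	4	3
C sp3	HCCl2	0.35	1	1
C sp3	HCBr2	0.88	1	1
C sp3	C4	0.20	32	27
C sp3	C3O	0.42	23	22
C sp3	C3N	0.21	1	1
C sp3	C2O2	1.06	1	1
C sp3	CF3	0.82	4	4
C sp3	CCl3	-0.03	1	1
C sp2	H2=C	0.09	31	30
C sp2	HC=C	0.20	84	57
C sp2	HC=N	0.48	2	2
C sp2	HC=O	0.05	21	21
C sp2	H=CO	0.27	9	8
C sp2	H=CS	0.39	18	11
C sp2	HO=O	-0.11	7	7
C sp2	C2=C	0.27	11	10
C sp2	C2=N	0.24	4	4
C sp2	C2=O	-0.51	62	62
C sp2	C=CO	0.21	7	6
C sp2	C=CS	0.64	5	4
C sp2	C=CBr	0.75	1	1
C sp2	CN=O	0.28	25	25
C sp2	CN=S	1.23	1	1
C sp2	CO=O	-0.04	122	116
C sp2	=CO2	0.18	1	1
C sp2	=CSCl	0.43	1	1
C aromatic	H:C2	0.23	2322	569
C aromatic	H:C:N	0.06	44	27
C aromatic	C:C2	0.29	485	362
C aromatic	:C3	0.23	44	22
C aromatic	C:C:N	0.00	8	8
C aromatic	:C2N	1.06	60	58
C aromatic	:C2N(+)	1.33	135	105
C aromatic	:C2:N	0.67	6	4
C aromatic	:C2O	0.48	360	282
C aromatic	:C2S	0.43	9	9
C aromatic	:C2F	0.52	75	39
C aromatic	:C2Cl	0.76	209	114
C aromatic	:C2Br	0.80	69	50
C aromatic	:C2J	1.18	13	11
C aromatic	:C:NF	0.02	5	3
C aromatic	:C:NCl	0.47	2	2
C aromatic	:C:NBr	0.67	1	1
C sp	H#C	0.09	8	8
C sp	C#C	0.17	14	11
C sp	C#N	-0.33	43	41
C sp	=N=S	0.87	1	1
N sp3	H2C	-0.61	3	3
N sp3	H2C(pi)	-0.90	66	65
N sp3	H2N	-0.05	1	1
N sp3	HC2(pi)	-0.93	5	5
N sp3	HC2(2pi)	-1.71	4	4
N sp3	HCN(pi)	0.00	1	1
N sp3	HCO(pi)	0.08	1	1
N sp3	C3	-0.54	3	1
N sp3	C3(pi)	-1.04	3	3
N sp2	C=C	0.00	1	1
N sp2	=CO	-0.43	6	6
N sp2	C=O	-0.07	1	1
N(+) sp2	CO=O(-)	-0.50	139	109
N aromatic	:C2	-0.29	33	30
O	HC	-1.05	163	149
O	HC(pi)	-0.07	295	254
O	C2	-1.12	4	3
O	C2(pi)	-0.60	182	165
O	HN	0.07	1	1
O	HN(pi)	0.01	6	6
O	C2(2pi)	-0.30	15	15
S2	HC	0.11	6	4
S2	C2	0.02	6	5
S2	C2(pi)	-0.10	6	6
S2	C2(2pi)	-0.15	13	11
S4	C2=O	-1.32	3	3
S4	C2=O2	-1.22	4	4
#stat	A	based_on		859
#stat	B	R2	0.8665	836
#stat	C	MAE	0.29	836
#stat	D	SD	0.39	836
#stat	E	k	10	810
#stat	F	Q2	0.8404	810
#stat	G	MAE_cv	0.31	810
#stat	H	SD_cv	0.42	810
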