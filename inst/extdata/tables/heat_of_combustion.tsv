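# descriptor: heat_of_combustion
# units: kJ/mol
backbone	neighbors	contribution	occurrences	molecules
B	C3	-4309.05	3	3
C sp3	H3B	439.88	3	1
C sp3	H3C	-773.83	2294	1153
C sp3	H3N	-1199.10	110	65
C sp3	H3N(+)	-817.94	3	3
C sp3	H3O	-1112.98	178	115
C sp3	H3S	-1396.74	23	19
C sp3	H3P	-1052.64	3	1
C sp3	H3Si	-1008.77	51	16
C sp3	H2BC	553.89	6	2
C sp3	H2C2	-652.47	4413	912
C sp3	H2CN	-1074.20	183	117
C sp3	H2CN(+)	-705.22	44	26
C sp3	H2CO	-980.99	610	374
C sp3	H2CS	-1274.78	106	72
C sp3	H2CP	-852.22	5	2
C sp3	H2CF	-623.15	8	7
C sp3	H2CCl	-617.40	51	42
C sp3	H2CBr	-623.39	22	19
C sp3	H2CJ	-685.52	10	8
C sp3	H2CSi	-932.85	22	13
C sp3	H2N2	-1480.52	9	2
C sp3	H2N2(+)	-807.51	1	1
C sp3	H2NO	-1375.72	1	1
C sp3	H2O2	-1279.46	11	9
C sp3	H2OCl	-951.95	3	2
C sp3	H2S2	-1932.88	5	3
C sp3	HC3	-529.62	363	254
C sp3	HC2N	-957.93	47	37
C sp3	HC2N(+)	-575.78	33	32
C sp3	HC2O	-850.09	277	138
C sp3	HC2S	-1152.31	20	16
C sp3	HC2F	-504.42	3	3
C sp3	HC2Cl	-497.94	10	10
C sp3	HC2Br	-500.70	9	7
C sp3	HC2J	-558.92	1	1
C sp3	HCN2	-1363.17	1	1
C sp3	HCN2(+)	-672.56	2	2
C sp3	HCO2	-1153.93	40	30
C sp3	HCF2	-433.94	8	7
C sp3	HCFCl	-472.96	4	4
C sp3	HCCl2	-494.62	9	8
C sp3	HCClBr	-518.18	1	1
C sp3	HCBr2	-476.37	1	1
C sp3	HN3(+)	-870.19	1	1
C sp3	HO3	-1433.08	4	4
C sp3	HOF2	-729.48	2	2
C sp3	C4	-403.80	117	91
C sp3	C3N	-813.97	13	10
C sp3	C3N(+)	-426.89	13	12
C sp3	C3O	-730.08	36	30
C sp3	C3S	-1023.12	15	12
C sp3	C3F	-179.93	2	2
C sp3	C3Cl	-361.21	2	2
C sp3	C3Br	-362.53	2	2
C sp3	C3J	-432.30	1	1
C sp3	C2N2(+)	-626.56	5	4
C sp3	C2O2	-1004.06	25	24
C sp3	C2F2	-320.26	60	15
C sp3	C2FCl	-318.84	2	1
C sp3	C2Cl2	-356.73	4	4
C sp3	CN3(+)	-746.41	6	4
C sp3	CO3	-1284.92	7	6
C sp3	COF2	-649.83	1	1
C sp3	CF3	-243.86	45	36
C sp3	CF2Cl	-302.73	8	6
C sp3	CF2Br	-320.46	5	4
C sp3	CFCl2	-323.43	5	5
C sp3	CFClBr	-275.67	1	1
C sp3	CCl3	-366.35	14	13
C sp3	CBr3	-339.39	1	1
C sp3	N4(+)	-896.07	1	1
C sp3	O4	-1580.14	2	2
C sp3	OF3	-531.65	2	2
C sp2	H2=C	-702.52	164	148
C sp2	H2=N	-928.80	1	1
C sp2	HC=C	-566.63	462	270
C sp2	HC=N	-762.24	14	13
C sp2	HC=O	-396.09	60	57
C sp2	H=CN	-958.41	32	24
C sp2	H=CN(+)	-595.08	3	3
C sp2	H=CO	-747.98	20	18
C sp2	H=CS	-1161.32	11	9
C sp2	H=CF	-546.98	2	2
C sp2	H=CCl	-555.33	6	5
C sp2	H=CBr	-573.39	2	2
C sp2	H=CSi	-833.05	3	3
C sp2	HN=N	-1134.46	18	15
C sp2	HN=O	-762.26	10	10
C sp2	H=NO	-916.53	2	2
C sp2	HO=O	-545.94	19	19
C sp2	H=NS	-1372.72	2	2
C sp2	C2=C	-433.99	125	97
C sp2	C2=N	-630.40	6	5
C sp2	C2=O	-248.77	94	78
C sp2	C=CN	-825.51	33	26
C sp2	C=CO	-602.48	16	16
C sp2	C=CS	-1031.71	3	3
C sp2	C=CF	-439.03	5	3
C sp2	C=CCl	-397.75	8	5
C sp2	CN=N	-991.99	17	16
C sp2	CN=O	-621.43	128	95
C sp2	CN=S	-1460.28	3	2
C sp2	CO=O	-389.60	500	370
C sp2	CO=O(-)	-534.91	49	45
C sp2	C=OS	-844.48	4	4
C sp2	C=OF	-174.28	1	1
C sp2	C=OCl	-205.80	8	7
C sp2	C=OBr	-204.22	2	2
C sp2	C=OJ	-281.70	2	2
C sp2	=CN2	-1249.51	8	8
C sp2	=CNO(+)	-678.42	2	2
C sp2	=COF	-430.57	2	2
C sp2	=CF2	-415.97	9	8
C sp2	=CFCl	-359.75	1	1
C sp2	=CCl2	-407.94	4	3
C sp2	=CJ2	-544.25	2	1
C sp2	N2=N	-1416.91	40	35
C sp2	N2=O	-1022.83	56	47
C sp2	N2=S	-1839.83	5	5
C sp2	N=NO	-1202.52	1	1
C sp2	NO=O	-772.08	7	7
C sp2	N=OS	-1488.48	1	1
C sp2	NS=S	-2092.99	3	2
C sp2	O2=O	-546.67	6	6
C sp2	O=OCl	-338.25	2	2
C aromatic	H:C2	-543.64	3345	599
C aromatic	H:C:N	-776.86	47	30
C aromatic	H:C:N(+)	-497.10	3	2
C aromatic	H:N2	-1022.16	2	2
C aromatic	:C3	-407.72	235	72
C aromatic	C:C2	-413.58	769	420
C aromatic	C:C:N	-630.62	38	17
C aromatic	C:C:N(+)	-361.54	1	1
C aromatic	:C2N	-844.05	161	113
C aromatic	:C2N(+)	-494.97	144	76
C aromatic	:C2:N	-644.82	19	13
C aromatic	:C2O	-619.12	122	93
C aromatic	:C2S	-1044.73	21	13
C aromatic	:C2F	-401.83	40	14
C aromatic	:C2Cl	-393.22	33	20
C aromatic	:C2Br	-399.84	4	4
C aromatic	:C2J	-468.14	17	14
C aromatic	:C2Si	-686.64	2	1
C aromatic	:CN:N	-1064.47	3	2
C aromatic	:C:NO	-835.98	5	3
C aromatic	N:N2	-1260.90	6	3
C aromatic	:N3	-583.18	3	3
C aromatic	:N2Cl	-828.48	1	1
C sp	H#C	-653.92	34	28
C sp	C#C	-506.41	55	34
C sp	C#N	-508.61	53	40
C sp	#CN	-1006.69	2	2
C sp	#CCl	-512.21	1	1
C sp	N#N	-912.20	2	2
C sp	#NO	-801.89	1	1
C sp	=C2	-554.47	6	6
C sp	=C=N	-741.19	2	2
C sp	=C=O	-323.55	1	1
C sp	=N=O	-433.06	5	4
C sp	=N=S	-1250.00	1	1
N sp3	H2C	144.43	49	44
N sp3	H2C(pi)	191.61	124	102
N sp3	H2N	-321.73	12	11
N sp3	H2N(pi)	-263.42	1	1
N sp3	H2S	-356.54	1	1
N sp3	HC2	657.84	30	28
N sp3	HC2(pi)	707.92	58	47
N sp3	HC2(2pi)	714.30	117	84
N sp3	HCN	209.21	3	2
N sp3	HCN(pi)	254.66	15	9
N sp3	HCN(2pi)	274.14	27	25
N sp3	HCN(+)(2pi)	382.93	3	3
N sp3	C3	1170.07	22	18
N sp3	C3(pi)	1214.78	27	22
N sp3	C3(2pi)	1214.87	24	13
N sp3	C3(3pi)	1229.16	2	2
N sp3	C2N	739.41	1	1
N sp3	C2N(pi)	781.06	1	1
N sp3	C2N(+)(pi)	919.58	6	4
N sp3	C2N(2pi)	771.90	16	13
N sp3	C2N(+)(2pi)	879.10	4	3
N sp3	C2N(3pi)	787.25	5	5
N sp3	C2Si	750.91	1	1
N sp3	C2Cl(2pi)	747.48	1	1
N sp3	C2Br(2pi)	769.45	1	1
N sp3	CN2(2pi)	384.22	6	4
N sp3	CN2(3pi)	424.65	1	1
N sp2	H=C	-7.70	8	8
N sp2	C=C	550.75	37	32
N sp2	C=N	310.59	28	14
N sp2	C=N(+)	237.35	11	11
N sp2	=CN	119.10	51	42
N sp2	=CN(+)	302.14	1	1
N sp2	C=O	396.97	5	5
N sp2	=CO	192.01	12	9
N sp2	N=N	-89.71	64	31
N sp2	N=O	-43.12	2	2
N sp2	O=O	356.35	2	2
N aromatic	H2:C(+)	-122.03	7	3
N aromatic	HC:C(+)	814.57	1	1
N aromatic	C2:C(+)	1314.74	1	1
N aromatic	:C2	412.85	64	47
N aromatic	:C:N	134.45	2	1
N(+) sp3	H3C	259.93	36	35
N(+) sp3	H2C2	381.05	4	4
N(+) sp3	HC3	531.03	6	3
N(+) sp2	CO=O(-)	116.31	218	116
N(+) sp2	C=NO(-)	139.32	1	1
N(+) sp2	NO=O(-)	-143.13	14	11
N(+) sp2	O2=O(-)	436.53	11	6
N(+) aromatic	H:C2	297.18	2	2
N(+) sp	C#C(-)	-520.51	2	2
N(+) sp	=N2(-)	-156.85	10	10
O	HC	389.05	437	219
O	HC(pi)	283.41	309	243
O	HN(pi)	-67.43	9	6
O	HO	-30.25	8	7
O	HS	-2.73	6	5
O	HSi	209.41	1	1
O	C2	778.41	245	141
O	C2(pi)	676.08	299	224
O	C2(2pi)	540.34	43	41
O	CN(pi)	0.00	2	2
O	CN(+)(pi)	0.00	11	6
O	CN(2pi)	242.71	3	3
O	CO	377.06	11	8
O	CO(pi)	233.20	11	9
O	CS	309.60	17	9
O	CP	386.05	13	5
O	CP(pi)	225.09	3	1
O	CSi	392.68	23	7
O	Si2	34.75	8	3
P3	C3	0.00	1	1
P4	C2O=O	-128.03	1	1
P4	C3=O	-172.02	1	1
P4	O3=O	8.54	5	5
S2	HC	-110.34	39	35
S2	HC(pi)	-117.44	3	3
S2	C2	629.97	40	36
S2	C2(pi)	613.04	7	7
S2	C2(2pi)	652.85	12	11
S2	CS	25.47	16	8
S2	CS(pi)	13.65	6	3
S4	C2=O	764.28	4	4
S4	C2=O2	1000.31	14	14
S4	CO=O2(-)	113.62	1	1
S4	NO=O2	2.73	1	1
S4	O2=O	-121.52	4	4
S4	O2=O2	89.44	6	6
S4	O=O2F	-120.52	1	1
S4	O=O2Cl	-114.10	1	1
Si	H3C	-1004.63	4	4
Si	H2C2	-581.65	2	2
Si	HC3	-193.18	2	2
Si	HC2Cl	-561.69	1	1
Si	HCCl2	-414.48	1	1
Si	HO3	-463.15	1	1
Si	C4	130.90	3	3
Si	C3N	0.00	1	1
Si	C3O	-97.16	3	2
Si	C3Cl	70.09	1	1
Si	C3Br	57.55	1	1
Si	C2O2	38.94	8	3
Si	C2Cl2	-0.66	4	4
Si	CO3	8.62	6	5
Si	CCl3	-133.90	1	1
H	H Acceptor	1.25	100	80
H	.H	-1.22	1623	467
H	..H	-1.09	2258	595
Angle60		-38.45	120	38
Angle90		-25.28	186	87
Angle102		-5.65	469	184
#stat	A	based_on		2151
#stat	B	R2	1	2031
#stat	C	MAE	16	2031
#stat	D	SD	22.93	2031
#stat	E	k	10	1965
#stat	F	Q2	0.9999	1965
#stat	G	MAE_cv	17.5	1965
#stat	H	SD_cv	25.2	1965
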