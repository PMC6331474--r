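state	H3K4me1	H3K4me2	H3K4me3	H3K9ac	H3K27ac	H4K20me1	H3K79me2	H3K36me3	H3K9me3	H3K27me3	H2A.Z	DNase
1_TssA	42	95	99	97	68	10	15	5	1	2	90	99
2_PromU	88	96	93	90	83	12	22	4	1	5	85	97
3_PromD1	70	90	95	85	60	10	20	5	1	8	80	95
4_PromD2	65	85	90	78	55	12	18	6	2	10	75	92
5_Tx5p	30	25	20	22	28	35	80	70	2	2	15	30
6_Tx	12	8	5	8	10	40	85	92	3	1	5	12
7_Tx3p	10	7	4	7	9	45	70	95	3	1	4	10
8_TxWk	8	5	3	5	6	20	35	55	4	2	3	8
9_TxReg	90	80	40	75	88	30	70	60	2	1	45	85
10_TxEnh5p	85	72	30	70	80	28	75	65	2	1	40	80
11_TxEnh3p	70	55	22	55	72	30	60	78	2	1	30	70
12_TxEnhW	50	40	15	35	48	22	45	55	3	2	20	50
13_EnhA1	97	92	35	88	96	15	25	12	1	1	70	95
14_EnhA2	92	85	28	80	90	14	20	10	1	2	60	90
15_EnhAF	89	78	22	70	84	16	28	18	1	2	50	85
16_EnhW1	80	60	15	40	55	12	15	8	2	4	35	70
17_EnhW2	68	45	10	28	40	10	12	6	2	5	25	55
18_EnhAc	60	55	18	60	85	10	14	7	1	3	40	75
19_DNase	45	40	18	30	35	8	10	5	2	4	55	96
20_ZNF_Rpts	10	6	4	5	8	15	25	40	70	5	5	10
21_Het	4	2	1	2	3	8	5	6	90	10	2	4
22_PromP	55	70	80	50	45	10	15	5	3	40	70	85
23_PromBiv	50	65	85	40	30	8	12	4	4	88	65	80
24_ReprPC	15	12	10	8	8	5	4	3	10	92	20	25
25_Quies	3	2	1	1	2	4	3	2	5	8	2	5
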