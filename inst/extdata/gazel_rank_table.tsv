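feature	RF-MdAcc	RF-MdGini	Cor-RF-MdGini	Cor-RF-MdAcc	Cor-RF-RFE-Acc	Cor-RF-RFE-Kap	MI-SVM-RFE-Acc	MI-SVM-RFE-Kap	SVM-RFE-W	ANOVA-p
m/z 145	1	1	1	2	46	53	100	125	323	2
m/z 97	2	2	3	1	142	185	63	67	159	3
m/z 325	5	5	7	5	210	220	38	37	1118	8
m/z 268	9	6	NA	NA	NA	NA	168	181	22	4
m/z 263	8	7	5	7	198	249	28	27	166	5
m/z 219	13	13	13	12	84	76	61	65	1022	12
m/z 162	104	31	20	26	211	221	39	38	103	17
m/z 288	167	36	25	29	140	152	NA	NA	976	22
m/z 148	43	47	27	86	87	98	66	70	471	38
m/z 198	101	71	150	496	48	36	70	84	167	34
m/z 167	48	50	45	24	505	586	144	154	13	39
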