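region	bin	A00	A0	A1	A2_3	B	DE	CF	R1
A	1	18	16	9	27	30	43	28	3
B	2	1	0	0	6	0	5	2	1
C	3	23	13	7	27	40	34	50	23
C	4	20	15	12	21	27	35	39	13
C	5	23	4	9	17	15	34	41	16
C	6	18	10	5	24	33	46	43	15
C	7	32	28	15	37	46	59	57	21
C	8	31	21	8	23	24	46	41	14
C	9	20	9	10	32	29	45	41	13
D	10	16	18	4	22	27	39	30	10
D	11	13	12	7	33	22	31	37	15
D	12	16	13	6	27	23	30	29	12
D	13	12	13	3	30	29	45	43	10
D	14	21	14	12	23	25	37	34	13
E	15	18	12	8	29	26	40	31	10
E	16	23	14	2	23	25	34	40	12
E	17	29	11	7	47	39	50	53	20
E	18	26	13	5	33	27	35	54	22
E	19	33	6	7	37	27	41	41	18
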