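region	bin	deep	intermediate	rho20	len10
A	1	16	111	32	10
B	2	1	8	4	1
C	3	14	126	38	19
C	4	21	106	31	10
C	5	9	79	36	19
C	6	10	117	40	16
C	7	36	172	41	21
C	8	21	113	38	18
C	9	17	117	42	24
D	10	19	102	28	10
D	11	16	99	31	16
D	12	12	82	38	24
D	13	19	124	26	12
D	14	16	88	44	23
E	15	17	105	30	18
E	16	15	90	35	19
E	17	24	148	47	19
E	18	23	108	45	28
E	19	17	111	38	23
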