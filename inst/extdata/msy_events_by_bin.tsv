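region	bin	effective_bases	all_abs	all_tr	all_tv	cpg_abs	cpg_tr	cpg_tv	noncpg_abs	noncpg_tr	noncpg_tv
A	1	91454	178	111	67	20	19	1	158	92	66
B	2	8275	15	8	7	2	2	0	13	6	7
C	3	79812	199	126	73	27	26	1	172	100	72
C	4	79655	178	108	70	20	17	3	158	91	67
C	5	79642	147	91	56	13	11	2	134	80	54
C	6	79674	185	105	80	18	16	2	167	89	78
C	7	78966	279	172	107	55	53	2	224	119	105
C	8	79820	201	141	60	29	28	1	172	113	59
C	9	80846	196	123	73	16	16	0	180	107	73
D	10	83305	165	114	51	19	17	2	146	97	49
D	11	83295	157	98	59	17	16	1	140	82	58
D	12	82726	150	92	58	16	16	0	134	76	58
D	13	83244	181	121	60	20	18	2	161	103	58
D	14	83106	169	103	66	15	13	2	154	90	64
E	15	84781	172	106	66	17	15	2	155	91	64
E	16	84043	164	109	55	19	18	1	145	91	54
E	17	84363	252	153	99	30	28	2	222	125	97
E	18	83940	202	133	69	22	20	2	180	113	67
E	19	84565	200	131	69	21	18	3	179	113	66
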