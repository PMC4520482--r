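region	bin	initial_pos	final_pos	genomic_span	n_fragments	effective_bases	gene_pct	cpg_positions	rep_score_bg02
A	1	2690918	2910156	219239	285	91454	6.20	1318	1.14
B	2	6655517	6673365	17849	33	8275	0	70	-0.30
C	3	7540768	7671720	130953	289	79812	0.56	1028	-0.77
C	4	7671760	7945341	273582	394	79655	0.31	584	-0.87
C	5	7946953	8156861	209909	457	79642	0	1004	-0.71
C	6	8156863	8382932	226070	397	79674	0	660	-0.72
C	7	8383002	8489128	106127	186	78966	0	1090	-0.93
C	8	8489176	8595654	106479	147	79820	0.62	1222	-0.78
C	9	8595830	8739563	143734	257	80846	0.77	832	-0.49
D	10	14629906	14887780	257875	256	83305	6.64	1184	1.28
D	11	14888375	15056945	168571	218	83295	13.54	1090	1.46
D	12	15056995	15436522	379528	332	82726	3.52	710	1.21
D	13	15436558	15727001	290444	282	83244	5.42	952	0.18
D	14	15730403	15957784	227382	291	83106	2.00	1292	-0.16
E	15	18553309	18714071	160763	246	84781	0	614	-0.62
E	16	18714094	18912763	198670	292	84043	0	550	-0.56
E	17	18912843	19148792	235950	330	84363	0	634	-0.66
E	18	19148988	19343219	194232	309	83940	0	622	-0.85
E	19	19343595	19549929	206335	273	84565	0	638	-0.68
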