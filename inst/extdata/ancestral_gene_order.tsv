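position	name	strand	type
1	trnI	J	tRNA
2	trnQ	N	tRNA
3	trnM	J	tRNA
4	ND2	J	PCG
5	trnW	J	tRNA
6	trnC	N	tRNA
7	trnY	N	tRNA
8	CO1	J	PCG
9	trnL2	J	tRNA
10	CO2	J	PCG
11	trnK	J	tRNA
12	trnD	J	tRNA
13	ATP8	J	PCG
14	ATP6	J	PCG
15	CO3	J	PCG
16	trnG	J	tRNA
17	ND3	J	PCG
18	trnA	J	tRNA
19	trnR	J	tRNA
20	trnN	J	tRNA
21	trnS1	J	tRNA
22	trnE	J	tRNA
23	trnF	N	tRNA
24	ND5	N	PCG
25	trnH	N	tRNA
26	ND4	N	PCG
27	ND4L	N	PCG
28	trnT	J	tRNA
29	trnP	N	tRNA
30	ND6	J	PCG
31	CYTB	J	PCG
32	trnS2	J	tRNA
33	ND1	N	PCG
34	trnL1	N	tRNA
35	lrRNA	N	rRNA
36	trnV	N	tRNA
37	srRNA	N	rRNA
38	CR	J	control_region
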