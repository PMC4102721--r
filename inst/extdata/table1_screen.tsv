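# machine-readable transcription of the published BAC library screen summary
# n_total counts distinct putative clones per assay (an ambiguous clone is
# counted once); n_allele1/n_allele2 count per assay nucleotide (an ambiguous
# clone appears under both), so the two accountings differ by the number of
# ambiguous clones.
assay_id	nt1_base	n_allele1	nt2_base	n_allele2	n_total
386-17c	C	87	G	8	95
386-17a	T	51	C	9	60
386-14d	A	0	G	2	2
386-14c	A	126	G	3	129
386-13	A	108	G	2	110
386-8	C	400	T	6	406
637-3	T	209	G	6	215
637-5	C	233	A	10	243
637-8a	T	336	C	66	402
637-8b	C	172	T	42	214
637-11	G	427	A	111	538
11428	A	142	T	52	194
11426	A	145	G	91	236
11424	T	3124	A	0	3124
11411	T	79	G	23	102
11410	A	67	T	13	80
11406	A	58	G	8	66
11405	G	54	T	14	68
11396	C	22	G	0	22
11395	G	11	A	5	16
11392a	T	7	C	0	7
11392b	A	10	C	10	20
11385-b	G	10	A	11	21
11385-c	G	11	T	16	27
11382a	T	31	C	36	67
11382b	G	36	C	32	68
11376	A	44	T	362	406
11372	A	607	C	0	607
11356	A	2	G	58	60
11355	A	98	G	84	182
11354	T	82	G	350	432
479-18	G	65	C	79	143
479-13d	G	51	A	9	60
479-13b	A	52	G	8	60
479-12b	G	121	T	4	125
479-12a	T	118	C	5	123
479-9	A	152	G	0	152
479-3	A	278	G	8	286
BolI-5	T	297	C	4	301
BolI-3	C	298	T	0	298
11308	T	201	C	177	377
11307	C	118	T	91	209
11303	G	0	A	0	0
11301	T	0	C	1	1
217-1	A	19	G	98	117
217-5	A	741	G	0	741
217-6a	C	17	A	14	31
217-6b	G	488	T	10	498
217-7	C	74	G	53	127
217-9	G	64	A	32	96
578-5	A	63	G	32	95
578-6	A	105	C	23	128
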