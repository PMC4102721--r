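# selected rows of the published assay-nucleotide assignment table
# (reference-panel genotype evidence); published_category is the category
# superscript printed for the assay ("" where none was assigned).
# "nd" / "-" denote missing calls; two-base codes are heterozygous calls.
assay_id	published_category	rapa_acc1	rapa_acc2	rapa_wgs	ole_acc1	ole_acc2	ole_wgs	ole_gss	express_call	express_amplicon	bac_a	bac_c
386-17c	1	C	C	C	G	G	G	-	C/G	S	C	G
386-8	2	C	C	C	T	C	T	-	T/C	Y	C	T
637-5	2	A/C	C	A	A	A	A	-	A/C	M	C	A
637-11	1	G	G	G	A	A	A	-	A/G	R	G	A
11424	5	A	A	A	T	T	T	T	T	T	T	T
11411	3	T/G	T	T	G	T	T	T	T/G	K	T	G
11406	3	A	A	A	A	A	A	A	A/G	R	A	G
11396	5	C	C	C	C	C	C	G	C	C	C	C
11410	2	A	A	A	A	A	A	T	A/T	W	A	T
479-18	1	G	G	G	C	C	C	-	nd	S	G	C
479-12b	2	G	T	G	T	T	T	-	T/G	K	G	T
479-12a	3	T	T	T	T	T	T	-	T/C	Y	T	C
217-6b	2	G	G	G	nd	nd	T	-	nd	K	G	T
217-6a	3	A	A	A	A	A	A	-	A/C	M	C	A
11356	3	nd	-	A	G	G	A	G	A/G	nd	A	G
479-13d	2	G	A/G	A	A	A	A	-	A/G	R	G	A
11303	unassigned	nd	nd	G	nd	nd	A	A	nd	nd	G	G
479-9	4	nd	G	G	A	A	A	-	A	A	A	nd
BolI-3	4	C	C	C	T	T	T	-	C	C	C	nd
386-14d	4	A	-	A	G	G	G	-	G	S	C	G
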