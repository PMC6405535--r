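# SNP alignment over the rrnS (12S rRNA) gene of the same five individuals
# as snp_cytb.tsv. Positions are 1-based on the rrnS alignment; '-' is an
# alignment gap, '.' means identical to the reference (GU188273, first
# individual column). Transcribed cell-by-cell from the published alignment
# table.
position	GU188273	KP015198	KR149448	MG437197	KT626655
68	-	-	-	C	C
75	-	-	-	T	T
76	-	-	-	T	T
77	-	-	-	A	A
78	-	-	-	T	T
79	-	-	-	T	T
93	A	G	.	.	.
94	C	T	.	.	.
119	T	G	.	.	.
164	C	.	.	T	T
175	A	.	G	.	.
191	G	.	.	C	C
192	G	.	.	A	A
255	A	.	.	G	G
264	C	.	.	A	A
266	A	.	.	T	T
287	T	.	.	C	C
303	T	.	.	C	C
424	A	.	.	C	C
425	T	.	.	C	C
485	T	.	A	A	A
511	-	-	A	A	A
521	A	.	.	T	T
524	T	.	A	A	A
544	C	.	.	T	T
584	T	.	A	A	A
665	T	.	C	C	C
778	A	.	T	T	T
791	G	.	A	A	A
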