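# SNP alignment over the Cytb (COB) gene of one H. armigera reference
# (GU188273), the two GenBank "H. assulta" mitogenomes under scrutiny
# (KP015198, KR149448) and two verified H. assulta individuals (MG437197,
# KT626655). Positions are 1-based relative to the Cytb CDS start; '.'
# means identical to the reference (first individual column). Transcribed
# cell-by-cell from the published alignment table.
position	GU188273	KP015198	KR149448	MG437197	KT626655
3	C	.	T	T	T
18	C	.	T	T	T
37	A	.	G	G	G
38	A	.	G	G	G
112	T	.	C	C	C
135	C	.	A	A	A
136	T	.	C	C	C
156	C	.	T	T	T
172	T	.	A	A	A
189	A	.	T	.	.
195	T	.	C	C	C
216	C	.	T	T	T
223	T	.	C	C	C
234	C	.	T	T	T
246	C	.	T	T	T
258	C	.	T	T	T
267	C	.	T	T	T
271	G	.	A	A	A
273	A	.	T	T	T
277	T	.	A	A	A
309	T	.	A	A	A
332	T	.	C	C	C
355	C	.	.	T	T
369	A	.	.	T	T
450	C	.	.	T	T
462	T	.	.	G	G
495	C	.	.	T	T
498	A	.	.	G	G
507	C	.	.	T	T
534	T	.	.	C	C
576	T	.	.	C	C
579	T	.	.	C	C
591	T	.	.	C	C
594	C	.	.	T	T
612	C	.	.	T	T
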