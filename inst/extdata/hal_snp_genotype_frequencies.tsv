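snp	location	pos	alleles	f11	f12	f22	maf_printed	hwe_p_printed	n
ss974768522	Promoter	64547553	C>T	0.426	0.468	0.106	0.339	0.253	638
ss974768523	Exon1	64547394	T>C	0.527	0.385	0.086	0.281	0.257	638
ss974768524	Intron2	64546261	T>C	0.588	0.323	0.089	0.251	0.0004	638
ss974768525	Exon5	64545391	C>T	0.647	0.314	0.039	0.196	0.898	638
ss974768527	Exon8	64543949	G>A	0.523	0.389	0.088	0.282	0.307	638
ss974768529	Intron11	64537682	A>G	0.078	0.378	0.544	0.267	0.370	638
ss974768531	Intron17	64529509	T>C	0.433	0.481	0.086	0.327	0.018	638
ss974768533	UTR3	64525640	C>A	0.091	0.433	0.476	0.307	0.680	638
ss974768534	UTR3	64524579	C>T	0.486	0.420	0.094	0.304	0.850	638
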