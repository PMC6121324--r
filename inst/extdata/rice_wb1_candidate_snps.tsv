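chrom	pos	ref	alt	delta	gene_id	effect	aa_change	gene_annotation
chr04	21550665	T	G	0.758	ORF1	missense	T>P	Helicase conserved C-terminal domain containing protein
chr04	21550664	G	T	0.754	ORF1	missense	T>K	Helicase conserved C-terminal domain containing protein
chr04	21550888	C	T	0.663	ORF1	intron		Helicase conserved C-terminal domain containing protein
chr04	21550286	T	A	0.655	ORF1	missense	T>S	Helicase conserved C-terminal domain containing protein
chr04	21551279	G	A	0.649	ORF1	intron		Helicase conserved C-terminal domain containing protein
chr04	21539737	A	G	0.754	ORF2	three_prime_utr		Protein of unknown function DUF668 family protein
chr04	21539457	G	T	0.612	ORF2	splice_region		Protein of unknown function DUF668 family protein
chr04	21331260	G	A	0.743	ORF3	missense	D>N	40S ribosomal protein S10
chr04	21514382	C	T	0.734	ORF4	intron		Similar to H0315E07.10 protein
chr04	21513793	A	G	0.708	ORF4	intron		Similar to H0315E07.10 protein
chr04	21612944	C	A	0.734	ORF5	missense	K>N	CENP-E-like kinetochore protein
chr04	21610862	C	A	0.663	ORF5	missense	S>I	CENP-E-like kinetochore protein
chr04	20423829	G	A	0.733	ORF6	missense	A>T	Glycosyl hydrolases
chr04	21795109	G	A	0.733	ORF7	missense	L>F	Expressed protein
chr04	21493980	G	A	0.672	ORF8	intron		Similar to H0315E07.7 protein
chr04	21897538	C	T	0.639	ORF9	three_prime_utr		Nonsense-mediated decay UPF3
chr04	21970357	C	T	0.634	ORF10	five_prime_utr		Peptide transporter PTR2
chr04	21710470	C	G	0.631	ORF11	intron		Conserved hypothetical protein
chr04	21734385	C	T	0.61	ORF12	nonsense	R>*	No apical meristem protein
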