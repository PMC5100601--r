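# synthetic S. cerevisiae-like cytoplasmic tRNA complement
# gene copy numbers approximate; decoded codons from standard wobble rules
# columns: name anticodon amino_acid gene_copy_number relative_abundance decoded_codons
name	anticodon	amino_acid	gene_copy_number	relative_abundance	decoded_codons
tRNA-Ala-AGC	AGC	A	11	11	GCT,GCC
tRNA-Ala-UGC	UGC	A	5	5	GCA,GCG
tRNA-Arg-ACG	ACG	R	6	6	CGT,CGC,CGA
tRNA-Arg-CCG	CCG	R	1	1	CGG
tRNA-Arg-UCU	UCU	R	11	11	AGA
tRNA-Arg-CCU	CCU	R	1	1	AGG
tRNA-Asn-GUU	GUU	N	10	10	AAT,AAC
tRNA-Asp-GUC	GUC	D	16	16	GAT,GAC
tRNA-Cys-GCA	GCA	C	4	4	TGT,TGC
tRNA-Gln-UUG	UUG	Q	9	9	CAA
tRNA-Gln-CUG	CUG	Q	1	1	CAG
tRNA-Glu-UUC	UUC	E	14	14	GAA
tRNA-Glu-CUC	CUC	E	2	2	GAG
tRNA-Gly-GCC	GCC	G	16	16	GGT,GGC
tRNA-Gly-UCC	UCC	G	3	3	GGA
tRNA-Gly-CCC	CCC	G	2	2	GGG
tRNA-His-GUG	GUG	H	7	7	CAT,CAC
tRNA-Ile-AAU	AAU	I	13	13	ATT,ATC
tRNA-Ile-UAU	UAU	I	2	2	ATA
tRNA-Leu-CAA	CAA	L	10	10	TTG
tRNA-Leu-UAA	UAA	L	7	7	TTA
tRNA-Leu-UAG	UAG	L	3	3	CTA,CTG
tRNA-Leu-GAG	GAG	L	1	1	CTT,CTC
tRNA-Lys-CUU	CUU	K	14	14	AAG
tRNA-Lys-UUU	UUU	K	7	7	AAA
tRNA-Met-CAU	CAU	M	5	5	ATG
tRNA-iMet-CAU	CAU	M	5	5	ATG
tRNA-Phe-GAA	GAA	F	10	10	TTT,TTC
tRNA-Pro-AGG	AGG	P	10	10	CCT,CCC,CCA
tRNA-Pro-UGG	UGG	P	2	2	CCG
tRNA-Ser-AGA	AGA	S	11	11	TCT,TCC,TCA
tRNA-Ser-CGA	CGA	S	1	1	TCG
tRNA-Ser-UGA	UGA	S	3	3	TCA
tRNA-Ser-GCU	GCU	S	4	4	AGT,AGC
tRNA-Thr-AGU	AGU	T	11	11	ACT,ACC,ACA
tRNA-Thr-UGU	UGU	T	2	2	ACA
tRNA-Thr-CGU	CGU	T	1	1	ACG
tRNA-Trp-CCA	CCA	W	6	6	TGG
tRNA-Tyr-GUA	GUA	Y	8	8	TAT,TAC
tRNA-Val-AAC	AAC	V	14	14	GTT,GTC,GTA
tRNA-Val-UAC	UAC	V	2	2	GTG
tRNA-Val-CAC	CAC	V	2	2	GTG
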