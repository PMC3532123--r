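chrom	pos	ref	alt	a	b	c	d	in_dbsnp	on_chip	functional_class	maf	sample_id	seq_genotype
7	43917013	A	G	11	2	20	0	1	1	NA	NA	S01	het
14	95923670	T	C	16	2	10	0	1	1	NA	NA	S01	het
19	57088850	A	C	8	2	16	0	1	1	NA	NA	S01	het
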