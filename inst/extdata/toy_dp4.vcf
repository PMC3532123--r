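##fileformat=VCFv4.2
##INFO=<ID=DP4,Number=4,Type=Integer,Description="Per-strand depths: ref-fwd,ref-rev,alt-fwd,alt-rev">
##FILTER=<ID=LowQual,Description="Low quality">
##contig=<ID=7>
##contig=<ID=14>
##contig=<ID=19>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
7	43917013	.	A	G	50	PASS	DP4=11,20,2,0
14	95923670	.	T	C	50	PASS	DP4=16,10,2,0
19	57088850	.	A	C	50	LowQual	DP4=8,16,2,0
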