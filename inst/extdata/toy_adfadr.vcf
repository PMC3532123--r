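##fileformat=VCFv4.2
##INFO=<ID=ADF,Number=R,Type=Integer,Description="Forward-strand allele depths (ref, alts)">
##INFO=<ID=ADR,Number=R,Type=Integer,Description="Reverse-strand allele depths (ref, alts)">
##contig=<ID=1>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
1	100	.	C	T,G	50	PASS	ADF=10,4,1;ADR=10,3,0
1	200	.	A	G	50	PASS	ADF=12,0;ADR=14,0
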