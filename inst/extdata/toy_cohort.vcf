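##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=A,Type=String,Description="Gene symbol per alt allele">
##INFO=<ID=CSQ,Number=A,Type=String,Description="Consequence class per alt allele">
##INFO=<ID=EA,Number=A,Type=Float,Description="Evolutionary Action score per alt allele">
##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency per alt allele">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##contig=<ID=1,length=1000000>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3	S4
1	100	.	A	G	.	PASS	GENE=GA;CSQ=missense;EA=80;AF=0.1	GT	0/1	0/0	1/1	0/0
1	200	.	C	T	.	PASS	GENE=GA;CSQ=missense;EA=30;AF=0.2	GT	0/0	0/1	0/0	0/0
1	300	.	A	G,T	.	PASS	GENE=GB,GB;CSQ=missense,other;EA=70,12;AF=0.3,0.1	GT	0/0	0/1	0/0	0/2
1	5200	.	G	GA	.	PASS	GENE=GB;CSQ=stop_gained;EA=.;AF=0.05	GT	0/1	0/0	0/0	0/0
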