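##fileformat=VCFv4.2
##source=synthetic toy example (3 usable SNPs, 1 multiallelic, 1 indel, 1 missing AD)
##contig=<ID=chr1,length=1000000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	D_bulk	G_bulk
chr1	1000	.	A	T	50	PASS	.	GT:AD	0/0:10,0	1/1:0,12
chr1	2000	.	G	C	50	PASS	.	GT:AD	0/1:20,20	0/1:30,10
chr1	3000	.	C	G	50	PASS	.	GT:AD	0/1:40,20	1/1:5,55
chr1	4000	.	A	T,C	50	PASS	.	GT:AD	0/1:10,5,5	0/1:10,5,5
chr1	5000	.	AT	A	50	PASS	.	GT:AD	0/1:12,8	0/1:9,11
chr1	6000	.	T	G	50	PASS	.	GT:AD	0/1:15,15	.:.
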