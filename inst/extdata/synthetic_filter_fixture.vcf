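##fileformat=VCFv4.2
##source=medipr synthetic hand-built filter-cascade fixture (20 sites, 2 samples)
##contig=<ID=chr1,length=1000000>
##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">
##INFO=<ID=SRP,Number=1,Type=Integer,Description="Simple repeat periodicity">
##INFO=<ID=HPL,Number=1,Type=Integer,Description="Homopolymer length">
##INFO=<ID=DNL,Number=1,Type=Integer,Description="Dinucleotide repeat length">
##INFO=<ID=REP,Number=0,Type=Flag,Description="Overlaps annotated repeat or segmental duplication">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Ref and alt read depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2
chr1	1000	v01	A	G	.	.	MQ=60;HPL=2;DNL=0	GT:AD	./.:1,29	./.:30,0
chr1	2000	v02	C	T	.	.	MQ=40;HPL=2;DNL=0	GT:AD	./.:1,29	./.:30,0
chr1	3000	v03	G	A	.	.	MQ=39;HPL=2;DNL=0	GT:AD	./.:1,29	./.:30,0
chr1	4000	v04	T	C	.	.	MQ=60;HPL=8;DNL=0	GT:AD	./.:1,29	./.:30,0
chr1	5000	v05	A	T	.	.	MQ=60;HPL=9;DNL=0	GT:AD	./.:1,29	./.:30,0
chr1	6000	v06	C	G	.	.	MQ=60;HPL=2;DNL=14	GT:AD	./.:1,29	./.:30,0
chr1	7000	v07	G	C	.	.	MQ=60;HPL=2;DNL=15	GT:AD	./.:1,29	./.:30,0
chr1	8000	v08	T	A	.	.	MQ=60;SRP=8;HPL=2;DNL=0	GT:AD	./.:1,29	./.:30,0
chr1	9000	v09	A	C	.	.	MQ=60;SRP=9;HPL=2;DNL=0	GT:AD	./.:1,29	./.:30,0
chr1	10000	v10	C	A	.	.	MQ=60;HPL=3;DNL=2	GT:AD	./.:1,29	./.:30,0
chr1	11000	v11	G	T	.	.	MQ=60;HPL=2;DNL=0;REP	GT:AD	./.:1,29	./.:30,0
chr1	12000	v12	T	G	.	.	MQ=35;HPL=10;DNL=0	GT:AD	./.:1,29	./.:30,0
chr1	100000	v13	A	G	.	.	MQ=60;HPL=2;DNL=0	GT:AD	./.:15,15	./.:30,0
chr1	104000	v14	C	T	.	.	MQ=60;HPL=2;DNL=0	GT:AD	./.:15,15	./.:30,0
chr1	109999	v15	G	A	.	.	MQ=60;HPL=2;DNL=0	GT:AD	./.:15,15	./.:30,0
chr1	200000	v16	T	C	.	.	MQ=60;HPL=2;DNL=0	GT:AD	./.:15,15	./.:30,0
chr1	203000	v17	A	T	.	.	MQ=60;HPL=2;DNL=0	GT:AD	./.:15,15	./.:30,0
chr1	206000	v18	C	G	.	.	MQ=60;HPL=2;DNL=0	GT:AD	./.:15,15	./.:30,0
chr1	209000	v19	G	C	.	.	MQ=60;HPL=2;DNL=0	GT:AD	./.:15,15	./.:30,0
chr1	300000	v20	T	A	.	.	MQ=60;HPL=2;DNL=0	GT:AD	./.:30,0	./.:12,18
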