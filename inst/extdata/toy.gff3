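##gff-version 3
chr1	drsAPA	gene	1	2800	.	+	.	ID=g0001
chr1	drsAPA	mRNA	1	2800	.	+	.	ID=g0001.t1;Parent=g0001
chr1	drsAPA	exon	1	600	.	+	.	Parent=g0001.t1
chr1	drsAPA	exon	901	1300	.	+	.	Parent=g0001.t1
chr1	drsAPA	exon	1601	2800	.	+	.	Parent=g0001.t1
chr1	drsAPA	CDS	151	153	.	+	0	Parent=g0001.t1
chr2	drsAPA	gene	1	2800	.	-	.	ID=g0002
chr2	drsAPA	mRNA	1	2800	.	-	.	ID=g0002.t1;Parent=g0002
chr2	drsAPA	exon	1	1200	.	-	.	Parent=g0002.t1
chr2	drsAPA	exon	1501	1900	.	-	.	Parent=g0002.t1
chr2	drsAPA	exon	2201	2800	.	-	.	Parent=g0002.t1
chr2	drsAPA	CDS	2648	2650	.	-	0	Parent=g0002.t1
chr1	drsAPA	gene	4801	7600	.	+	.	ID=g0003
chr1	drsAPA	mRNA	4801	7600	.	+	.	ID=g0003.t1;Parent=g0003
chr1	drsAPA	exon	4801	5400	.	+	.	Parent=g0003.t1
chr1	drsAPA	exon	5701	6100	.	+	.	Parent=g0003.t1
chr1	drsAPA	exon	6401	7600	.	+	.	Parent=g0003.t1
chr1	drsAPA	CDS	4951	4953	.	+	0	Parent=g0003.t1
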