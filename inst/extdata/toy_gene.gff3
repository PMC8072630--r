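##gff-version 3
toychr	toy	gene	1	10	.	+	.	ID=g1
toychr	toy	mRNA	1	10	.	+	.	ID=t1;Parent=g1
toychr	toy	exon	1	4	.	+	.	ID=t1.exon1;Parent=t1
toychr	toy	exon	7	10	.	+	.	ID=t1.exon2;Parent=t1
toychr2	toy	gene	3	30	.	-	.	ID=g2
toychr2	toy	mRNA	3	30	.	-	.	ID=t2;Parent=g2
toychr2	toy	exon	3	10	.	-	.	ID=t2.exon2;Parent=t2
toychr2	toy	exon	18	30	.	-	.	ID=t2.exon1;Parent=t2
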