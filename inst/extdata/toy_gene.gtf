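toychr	toy	exon	1	4	.	+	.	gene_id "g1"; transcript_id "t1";
toychr	toy	exon	7	10	.	+	.	gene_id "g1"; transcript_id "t1";
toychr2	toy	exon	3	10	.	-	.	gene_id "g2"; transcript_id "t2";
toychr2	toy	exon	18	30	.	-	.	gene_id "g2"; transcript_id "t2";
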