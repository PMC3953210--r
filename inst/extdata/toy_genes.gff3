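##gff-version 3
chrA	toy	gene	10000	20500	.	+	.	ID=GENEA;Name=GENEA;biotype=protein_coding
chrA	toy	mRNA	10000	20500	.	+	.	ID=GENEA.t1;Parent=GENEA
chrA	toy	exon	10000	10500	.	+	.	ID=GENEA.t1.e1;Parent=GENEA.t1
chrA	toy	exon	14000	14500	.	+	.	ID=GENEA.t1.e2;Parent=GENEA.t1
chrA	toy	exon	20000	20500	.	+	.	ID=GENEA.t1.e3;Parent=GENEA.t1
chrA	toy	mRNA	10000	14500	.	+	.	ID=GENEA.t2;Parent=GENEA
chrA	toy	exon	10000	10500	.	+	.	ID=GENEA.t2.e1;Parent=GENEA.t2
chrA	toy	exon	14000	14500	.	+	.	ID=GENEA.t2.e2;Parent=GENEA.t2
chrB	toy	gene	50000	64500	.	-	.	ID=GENEB;Name=GENEB;biotype=non_coding
chrB	toy	mRNA	50000	64500	.	-	.	ID=GENEB.t1;Parent=GENEB
chrB	toy	exon	50000	50500	.	-	.	ID=GENEB.t1.e1;Parent=GENEB.t1
chrB	toy	exon	57000	57500	.	-	.	ID=GENEB.t1.e2;Parent=GENEB.t1
chrB	toy	exon	64000	64500	.	-	.	ID=GENEB.t1.e3;Parent=GENEB.t1
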