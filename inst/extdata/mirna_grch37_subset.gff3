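##gff-version 3
# miRBase hairpin loci (miRNA_primary_transcript), GRCh37 coordinates:
# the 24 genes implicated on chromosomes 1, 2 and 22.
1	.	miRNA_primary_transcript	98510798	98510907	.	-	.	ID=hsa-mir-2682;Name=hsa-mir-2682
1	.	miRNA_primary_transcript	98511626	98511727	.	-	.	ID=hsa-mir-137;Name=hsa-mir-137
1	.	miRNA_primary_transcript	1102484	1102578	.	+	.	ID=hsa-mir-200b;Name=hsa-mir-200b
1	.	miRNA_primary_transcript	1103243	1103332	.	+	.	ID=hsa-mir-200a;Name=hsa-mir-200a
1	.	miRNA_primary_transcript	1104385	1104467	.	+	.	ID=hsa-mir-429;Name=hsa-mir-429
2	.	miRNA_primary_transcript	240273419	240273499	.	-	.	ID=hsa-mir-2467;Name=hsa-mir-2467
2	.	miRNA_primary_transcript	242417320	242417397	.	+	.	ID=hsa-mir-3133;Name=hsa-mir-3133
2	.	miRNA_primary_transcript	111042430	111042520	.	+	.	ID=hsa-mir-4436b-2;Name=hsa-mir-4436b-2
2	.	miRNA_primary_transcript	239990513	239990610	.	-	.	ID=hsa-mir-4440;Name=hsa-mir-4440
2	.	miRNA_primary_transcript	240007523	240007622	.	-	.	ID=hsa-mir-4441;Name=hsa-mir-4441
2	.	miRNA_primary_transcript	240882432	240882511	.	-	.	ID=hsa-mir-4786;Name=hsa-mir-4786
2	.	miRNA_primary_transcript	110827538	110827619	.	-	.	ID=hsa-mir-4267;Name=hsa-mir-4267
2	.	miRNA_primary_transcript	110844010	110844100	.	-	.	ID=hsa-mir-4436b-1;Name=hsa-mir-4436b-1
2	.	miRNA_primary_transcript	240227157	240227240	.	+	.	ID=hsa-mir-4269;Name=hsa-mir-4269
2	.	miRNA_primary_transcript	241395418	241395506	.	+	.	ID=hsa-mir-149;Name=hsa-mir-149
22	.	miRNA_primary_transcript	20073269	20073356	.	+	.	ID=hsa-mir-3618;Name=hsa-mir-3618
22	.	miRNA_primary_transcript	20073581	20073665	.	+	.	ID=hsa-mir-1306;Name=hsa-mir-1306
22	.	miRNA_primary_transcript	22007270	22007347	.	+	.	ID=hsa-mir-301b;Name=hsa-mir-301b
22	.	miRNA_primary_transcript	22007593	22007674	.	+	.	ID=hsa-mir-130b;Name=hsa-mir-130b
22	.	miRNA_primary_transcript	19951276	19951357	.	+	.	ID=hsa-mir-4761;Name=hsa-mir-4761
22	.	miRNA_primary_transcript	20020662	20020743	.	+	.	ID=hsa-mir-185;Name=hsa-mir-185
22	.	miRNA_primary_transcript	20236657	20236734	.	-	.	ID=hsa-mir-1286;Name=hsa-mir-1286
22	.	miRNA_primary_transcript	21388465	21388561	.	-	.	ID=hsa-mir-649;Name=hsa-mir-649
22	.	miRNA_primary_transcript	23165270	23165365	.	+	.	ID=hsa-mir-650;Name=hsa-mir-650
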