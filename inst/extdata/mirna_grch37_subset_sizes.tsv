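# Recorded miRBase sizes (bp) for the 24 GRCh37 hairpin loci in
# mirna_grch37_subset.gff3 (size = end - start + 1).
gene_id	size_bp
hsa-mir-2682	110
hsa-mir-137	102
hsa-mir-200b	95
hsa-mir-200a	90
hsa-mir-429	83
hsa-mir-2467	81
hsa-mir-3133	78
hsa-mir-4436b-2	91
hsa-mir-4440	98
hsa-mir-4441	100
hsa-mir-4786	80
hsa-mir-4267	82
hsa-mir-4436b-1	91
hsa-mir-4269	84
hsa-mir-149	89
hsa-mir-3618	88
hsa-mir-1306	85
hsa-mir-301b	78
hsa-mir-130b	82
hsa-mir-4761	82
hsa-mir-185	82
hsa-mir-1286	78
hsa-mir-649	97
hsa-mir-650	96
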