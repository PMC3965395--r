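# Per-chromosome summary of the APL de novo CNV collection (GRCh37):
# fractional CNV coverage (R2 = union CNV length / chromosome length)
# and miRNA-gene hit counts, separately for Gains and Losses.
# N/A: no de novo CNVs of that type on the chromosome.
chrom	gain_r2	gain_hits	loss_r2	loss_hits
1	0.0241	5	0.0050	5
2	0.0009	0	0.0314	17
3	0.0041	1	0.0923	12
4	N/A	N/A	0.0886	4
5	N/A	N/A	0.0763	7
6	0.0019	0	0.0187	2
7	0.0103	4	0.1425	7
8	0.0068	0	0.0088	1
9	0.0371	9	0.0297	1
10	0.0822	4	0.0005	0
11	0.0002	0	0.0410	0
12	0.1691	13	0.1013	3
13	0.0009	0	0.0169	0
14	0.0006	0	N/A	N/A
15	0.1254	39	0.0742	7
16	0.0320	2	0.1032	9
17	0.0317	8	0.0256	1
18	0.0006	0	0.2618	2
19	N/A	N/A	0.0145	2
20	N/A	N/A	0.0301	2
21	0.0074	1	0.1183	3
22	0.0893	18	0.1473	24
X	0.0304	8	0.0406	1
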