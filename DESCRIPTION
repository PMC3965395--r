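Package: cnvMir
Title: Chromosome-Level Enrichment of microRNA Genes in De Novo Copy
    Number Variants
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects chromosomes in which microRNA genes are
    over-represented inside de novo copy number variants (CNVs). Maps
    miRBase-style miRNA annotations onto patient CNV calls, computes
    per-chromosome interval summaries (union lengths, fractional
    coverage ratios, overlap hit counts), and tests each
    chromosome/CNV-type combination against a Monte Carlo null in which
    every CNV keeps its length but is re-placed uniformly at random
    within its chromosome. Empirical upper-tail p-values are adjusted by
    the Benjamini-Hochberg false discovery rate procedure; an exact
    convolution of per-CNV hit distributions provides an analytic
    alternative to sampling on small instances. Includes a correlation
    analysis of hit counts against CNV coverage, a population-CNV
    (DGV-style) filter to nominate study-specific candidate miRNA genes,
    and a seeded synthetic-data generator for calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CopyNumberVariation, GenomeAnnotation, StatisticalMethod,
    Software
RoxygenNote: 7.3.3
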