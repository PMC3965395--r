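test_that("gene lengths follow the 1-based inclusive size convention", {
    expect_equal(geneLengths(IRanges::IRanges(98511626, 98511727)), 102L)
    expect_equal(geneLengths(IRanges::IRanges(98510798, 98510907)), 110L)
    expect_equal(geneLengths(IRanges::IRanges(7, 7)), 1L)
})

test_that("unionLength handles single, disjoint and merged intervals", {
    expect_equal(unionLength(IRanges::IRanges(100, 199)), 100)
    expect_equal(unionLength(IRanges::IRanges(c(100, 300), c(199, 399))),
        200)
    expect_equal(unionLength(IRanges::IRanges(integer(0), integer(0))), 0)
    # nested and chained overlaps
    expect_equal(unionLength(
        IRanges::IRanges(c(100, 150, 120), c(400, 250, 500))), 401)
})

test_that("unionLength equals per-base marking on random intervals", {
    set.seed(11)
    for (rep in 1:10) {
        x <- randomIntervals(50, 10000)
        expect_equal(unionLength(x),
            baseMarkingUnion(start(x), end(x), 10000))
        # and agrees with the IRanges reduce route
        expect_equal(unionLength(x),
            sum(IRanges::width(IRanges::reduce(x))))
    }
})

test_that("unionLength is invariant to permutation and interval splitting", {
    set.seed(12)
    x <- randomIntervals(30, 5000)
    u <- unionLength(x)
    expect_equal(unionLength(rev(x)), u)
    expect_equal(unionLength(x[sample(length(x))]), u)
    # split one interval into two adjacent touching halves
    i <- which(IRanges::width(x) >= 2)[1]
    mid <- start(x)[i] + IRanges::width(x)[i] %/% 2
    split <- c(x[-i], IRanges::IRanges(start(x)[i], mid - 1),
        IRanges::IRanges(mid, end(x)[i]))
    expect_equal(unionLength(split), u)
})

test_that("unionLength rejects mixed chromosomes or CNV types", {
    g <- GenomicRanges::GRanges(c("1", "2"),
        IRanges::IRanges(c(1, 1), c(10, 10)))
    expect_error(unionLength(g), "single chromosome")
    g2 <- GenomicRanges::GRanges("1", IRanges::IRanges(c(1, 20), c(10, 30)),
        cnv_type = c("Gain", "Loss"))
    expect_error(unionLength(g2), "single type")
})

test_that("overlap predicate is closed-interval intersection, not adjacency", {
    cnv <- GenomicRanges::GRanges("1", IRanges::IRanges(100, 5000))
    inside <- GenomicRanges::GRanges("1", IRanges::IRanges(4990, 5080))
    beyond <- GenomicRanges::GRanges("1", IRanges::IRanges(5001, 5090))
    expect_true(cnvOverlapsGene(cnv, inside))
    expect_false(cnvOverlapsGene(cnv, beyond))
    expect_error(cnvOverlapsGene(cnv,
        GenomicRanges::GRanges("2", IRanges::IRanges(1, 10))),
        "different chromosomes")
    # containment demands the whole gene inside the CNV
    expect_false(cnvOverlapsGene(cnv, inside, overlapMode = "containment"))
    expect_true(cnvOverlapsGene(cnv,
        GenomicRanges::GRanges("1", IRanges::IRanges(200, 300)),
        overlapMode = "containment"))
})

test_that("overlap predicate matches set intersection on all tiny pairs", {
    ends <- expand.grid(a1 = 1:6, a2 = 1:6, b1 = 1:6, b2 = 1:6)
    ends <- ends[ends$a1 <= ends$a2 & ends$b1 <= ends$b2, ]
    cnv <- GenomicRanges::GRanges("1", IRanges::IRanges(ends$a1, ends$a2))
    gene <- GenomicRanges::GRanges("1", IRanges::IRanges(ends$b1, ends$b2))
    got <- cnvOverlapsGene(cnv, gene)
    want <- mapply(setIntersectOverlap, ends$a1, ends$a2, ends$b1, ends$b2)
    expect_equal(got, unname(want))
})

test_that("countHits counts multiplicities and distinct genes", {
    genes <- GenomicRanges::GRanges("1", IRanges::IRanges(500, 599),
        gene_id = "mir-a")
    none <- GenomicRanges::GRanges(seqnames = character(0),
        ranges = IRanges::IRanges())
    expect_equal(countHits(none, genes), c(hits = 0, unique = 0))
    # one gene inside two distinct CNVs -> 2 hits, 1 unique
    cnvs <- GenomicRanges::GRanges("1",
        IRanges::IRanges(c(400, 550), c(1400, 2000)))
    expect_equal(countHits(cnvs, genes), c(hits = 2, unique = 1))
})

test_that("countHits equals the nested-loop oracle on random fixtures", {
    set.seed(13)
    for (rep in 1:5) {
        cnvs <- GenomicRanges::GRanges("1", randomIntervals(20, 50000, 3000))
        genes <- GenomicRanges::GRanges("1", randomIntervals(30, 50000, 120))
        for (mode in c("any", "containment")) {
            got <- countHits(cnvs, genes, overlapMode = mode)
            want <- nestedLoopHits(start(cnvs), end(cnvs),
                start(genes), end(genes), containment = mode == "containment")
            expect_equal(got, want)
        }
        # IRanges cross-check of the hits total under "any"
        expect_equal(unname(countHits(cnvs, genes)[["hits"]]),
            sum(IRanges::countOverlaps(cnvs, genes)))
    }
})

test_that("hits are additive over CNV partitions, unique subadditive, and monotone", {
    set.seed(14)
    cnvs <- GenomicRanges::GRanges("1", randomIntervals(16, 30000, 2500))
    genes <- GenomicRanges::GRanges("1", randomIntervals(25, 30000, 110))
    whole <- countHits(cnvs, genes)
    half <- seq_len(8)
    a <- countHits(cnvs[half], genes)
    b <- countHits(cnvs[-half], genes)
    expect_equal(a[["hits"]] + b[["hits"]], whole[["hits"]])
    expect_gte(a[["unique"]] + b[["unique"]], whole[["unique"]])
    # removing any CNV never increases hits or unique
    for (i in seq_along(cnvs)) {
        removed <- countHits(cnvs[-i], genes)
        expect_lte(removed[["hits"]], whole[["hits"]])
        expect_lte(removed[["unique"]], whole[["unique"]])
    }
})

test_that("summarizeCnvMirna computes ratios and propagates no-data rows", {
    ds <- toyGrangesDataset()
    summ <- summarizeCnvMirna(ds)
    expect_equal(nrow(summ), 4)  # 2 chromosomes x 2 types
    r1loss <- summ[summ$chrom == "1" & summ$cnv_type == "Loss", ]
    expect_equal(r1loss$L1, 200)          # two 100-bp genes
    expect_equal(r1loss$R1, 0.02)
    expect_equal(r1loss$n_cnvs, 2L)
    expect_equal(r1loss$L2, 2102)         # [400,1400] + [1500,2600]
    expect_equal(r1loss$hits, 2)          # mir-a and mir-b once each
    expect_equal(r1loss$unique, 2)
    # chromosome 1 has no Gains -> NA row
    r1gain <- summ[summ$chrom == "1" & summ$cnv_type == "Gain", ]
    expect_equal(r1gain$n_cnvs, 0L)
    expect_true(is.na(r1gain$L2) && is.na(r1gain$hits))
    # rows recompute through countHits independently
    for (i in which(summ$n_cnvs > 0)) {
        cc <- cnvCalls(ds)
        cc <- cc[as.character(seqnames(cc)) == summ$chrom[i] &
            cc$cnv_type == summ$cnv_type[i]]
        expect_equal(unname(countHits(cc, mirnaGenes(ds))[["hits"]]),
            summ$hits[i])
    }
    # invariants: ratios within [0,1], unique <= hits
    ok <- !is.na(summ$R2)
    expect_true(all(summ$R1 >= 0 & summ$R1 <= 1))
    expect_true(all(summ$R2[ok] >= 0 & summ$R2[ok] <= 1))
    expect_true(all(summ$unique[ok] <= summ$hits[ok]))
})
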