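test_that("BH adjustment matches the step-up formula and the independent reference", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
    expect_error(bhAdjust(c(0.1, -0.1)), "\\[0, 1\\]")
    set.seed(41)
    for (rep in 1:50) {
        p <- runif(sample(1:40, 1))
        expect_equal(bhAdjust(p), bhReference(p), tolerance = 1e-12)
    }
})

test_that("BH adjustment is monotone and exceeds raw p-values", {
    set.seed(42)
    p <- runif(30)
    adj <- bhAdjust(p)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
})

test_that("significance selection uses strict inequality at alpha", {
    res <- S4Vectors::DataFrame(
        chrom = c("1", "2", "22", "22b"),
        p_fdr = c(0.02309, 0.00449, 0.04349, 0.07785))
    sel <- selectSignificant(res, alpha = 0.05)
    expect_setequal(sel$chrom, c("1", "2", "22"))
    expect_equal(nrow(selectSignificant(
        S4Vectors::DataFrame(p_fdr = rep(1, 4)), alpha = 0.05)), 0)
    expect_equal(nrow(selectSignificant(res, alpha = 0)), 0)
    # p_fdr exactly at alpha is not significant
    expect_equal(nrow(selectSignificant(
        S4Vectors::DataFrame(p_fdr = 0.05), alpha = 0.05)), 0)
})

test_that("correlation reproduces the published per-chromosome values", {
    tab <- read.delim(system.file("extdata", "apl_chromosome_summary.tsv",
        package = "cnvMir"), comment.char = "#",
        na.strings = c("NA", "N/A"))
    summ <- S4Vectors::DataFrame(
        chrom = rep(tab$chrom, 2),
        cnv_type = rep(c("Gain", "Loss"), each = nrow(tab)),
        R2 = c(tab$gain_r2, tab$loss_r2),
        hits = c(tab$gain_hits, tab$loss_hits))
    gain <- correlateHitsCoverage(summ, "Gain")
    loss <- correlateHitsCoverage(summ, "Loss")
    expect_equal(gain@nPoints, 19L)
    expect_equal(loss@nPoints, 22L)
    expect_equal(gain@r, 0.75765, tolerance = 1e-3)
    expect_equal(loss@r, 0.32732, tolerance = 1e-3)
})

test_that("correlation handles collinear data, row order and affine maps", {
    base <- S4Vectors::DataFrame(
        cnv_type = "Gain", R2 = c(0.01, 0.02, 0.04, 0.08),
        hits = c(3, 5, 9, 17))  # hits = 1 + 200 * R2
    res <- correlateHitsCoverage(base, "Gain")
    expect_equal(res@r, 1)
    expect_equal(res@slope, 200)
    expect_equal(res@intercept, 1)
    shuffled <- base[c(3, 1, 4, 2), ]
    expect_equal(correlateHitsCoverage(shuffled, "Gain")@r, res@r)
    # r is invariant under separate positive affine maps of each variable
    mapped <- base
    mapped$R2 <- 3 * mapped$R2 + 0.5
    mapped$hits <- 10 * mapped$hits + 2
    expect_equal(correlateHitsCoverage(mapped, "Gain")@r, res@r)
})

test_that("correlation errors on too few points or zero variance", {
    small <- S4Vectors::DataFrame(cnv_type = "Loss", R2 = c(0.1, 0.2),
        hits = c(1, 2))
    expect_error(correlateHitsCoverage(small, "Loss"), ">= 3")
    flat <- S4Vectors::DataFrame(cnv_type = "Loss", R2 = c(0.1, 0.1, 0.1),
        hits = c(1, 2, 3))
    expect_error(correlateHitsCoverage(flat, "Loss"), "zero variance")
})

test_that("testEnrichment flags a planted chromosome and keeps N/A rows", {
    ds <- simulateDataset(
        chromLengths = c(`1` = 1e7, `2` = 1e7), nGenes = 10, nCnvs = 10,
        cnvTypes = "Loss", enrichment = c(`1` = 0.8), seed = 43)
    res <- testEnrichment(ds, nRealizations = 5000, seed = 7)
    expect_s4_class(res, "EnrichmentResults")
    expect_equal(nrow(res), 4)  # 2 chromosomes x 2 types
    gainRows <- res[res$cnv_type == "Gain", ]
    expect_true(all(is.na(gainRows$p_raw)))  # no Gain CNVs generated
    planted <- res[res$chrom == "1" & res$cnv_type == "Loss", ]
    background <- res[res$chrom == "2" & res$cnv_type == "Loss", ]
    expect_true(planted$significant)
    expect_true(planted$p_fdr >= planted$p_raw)
    expect_gt(background$p_raw, planted$p_raw)
    # identical seed reproduces identical p-values
    res2 <- testEnrichment(ds, nRealizations = 5000, seed = 7)
    expect_identical(res$p_raw, res2$p_raw)
})

test_that("exact and Monte Carlo enrichment tests agree on small data", {
    ds <- simulateDataset(chromLengths = c(`1` = 5e4), nGenes = 5,
        nCnvs = 3, cnvTypes = "Gain", cnvLengthRange = c(100, 2000),
        enrichment = 1, seed = 44)
    mc <- testEnrichment(ds, nRealizations = 2e4, seed = 8)
    ex <- testEnrichment(ds, exact = TRUE)
    i <- which(mc$n_cnvs > 0)
    pTrue <- ex$p_raw[i]
    se <- sqrt(pTrue * (1 - pTrue) / 2e4)
    expect_lt(abs(mc$p_raw[i] - pTrue), 3 * se + 1e-9)
})

test_that("candidates come from significant rows and population filtering flags overlaps", {
    ds <- simulateDataset(chromLengths = c(`1` = 1e6), nGenes = 12,
        nCnvs = 10, cnvTypes = "Loss", enrichment = 1, seed = 45)
    res <- testEnrichment(ds, nRealizations = 3000, seed = 9)
    cand <- enrichedCandidates(ds, res)
    expect_gt(length(cand), 0)
    # every candidate overlaps at least one CNV of the significant type
    cc <- cnvCalls(ds)
    for (i in seq_along(cand))
        expect_true(any(start(cc) <= end(cand[i]) &
            end(cc) >= start(cand[i])))
    # population CNVs overlapping all but two candidates
    keepOut <- c(1L, 2L)
    popTargets <- cand[-keepOut]
    pop <- GenomicRanges::GRanges(seqnames(popTargets), IRanges::IRanges(
        start(popTargets) - 50, end(popTargets) + 50),
        cnv_type = rep("Loss", length(popTargets)))
    flagged <- populationFilter(cand, pop)
    expect_equal(which(!flagged$in_population), keepOut)
    # nested-loop oracle over all (candidate, population CNV) pairs
    want <- vapply(seq_along(cand), function(i) {
        any(vapply(seq_along(pop), function(j)
            as.character(seqnames(pop[j])) ==
                as.character(seqnames(cand[i])) &&
            start(pop[j]) <= end(cand[i]) &&
            end(pop[j]) >= start(cand[i]), logical(1)))
    }, logical(1))
    expect_equal(flagged$in_population, want)
    # empty population: everything is study-specific
    none <- populationFilter(cand, GenomicRanges::GRanges())
    expect_false(any(none$in_population))
})
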