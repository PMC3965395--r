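# Independent brute-force oracles, deliberately implemented without any
# of the package's interval machinery so they can vouch for it.

# Union length by per-base boolean marking on a small chromosome.
baseMarkingUnion <- function(starts, ends, G) {
    covered <- logical(G)
    for (i in seq_along(starts))
        covered[starts[i]:ends[i]] <- TRUE
    sum(covered)
}

# Closed-interval overlap of two integer intervals via explicit
# set intersection.
setIntersectOverlap <- function(a1, a2, b1, b2) {
    length(intersect(seq(a1, a2), seq(b1, b2))) > 0
}

# hits/unique by a plain double loop over all (cnv, gene) pairs.
nestedLoopHits <- function(cs, ce, gs, ge, containment = FALSE) {
    hits <- 0L
    hit <- logical(length(gs))
    for (i in seq_along(cs)) {
        for (j in seq_along(gs)) {
            ov <- if (containment) cs[i] <= gs[j] && ce[i] >= ge[j]
                else cs[i] <= ge[j] && ce[i] >= gs[j]
            if (ov) {
                hits <- hits + 1L
                hit[j] <- TRUE
            }
        }
    }
    c(hits = hits, unique = sum(hit))
}

# Exact pmf of total hits by full Cartesian enumeration of all start
# tuples (feasible only for tiny G and few CNVs).
cartesianHitPmf <- function(cnvLengths, gs, ge, G) {
    startSets <- lapply(cnvLengths, function(L) seq_len(G - L + 1))
    grid <- expand.grid(startSets)
    tot <- integer(nrow(grid))
    for (k in seq_along(cnvLengths)) {
        s <- grid[[k]]
        e <- s + cnvLengths[k] - 1
        for (j in seq_along(gs))
            tot <- tot + as.integer(s <= ge[j] & e >= gs[j])
    }
    tb <- table(tot) / nrow(grid)
    p <- as.numeric(tb)
    names(p) <- names(tb)
    p
}

# Benjamini-Hochberg step-up by literal sort-and-cumulative-minimum,
# coded independently of stats::p.adjust.
bhReference <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- numeric(m)
    running <- Inf
    for (i in m:1) {
        running <- min(running, ps[i] * m / i)
        adj[i] <- min(running, 1)
    }
    out <- numeric(m)
    out[o] <- adj
    out
}

# Random toy dataset pieces used across tests.
randomIntervals <- function(n, G, maxLen = 500) {
    s <- sample.int(G, n, replace = TRUE)
    len <- sample.int(maxLen, n, replace = TRUE)
    e <- pmin(G, s + len - 1)
    IRanges::IRanges(s, e)
}

toyGenes <- function() {
    IRanges::IRanges(c(2000, 4000, 6000, 8000, 9500),
        width = c(80, 90, 100, 110, 85))
}

toyGrangesDataset <- function() {
    gnm <- GenomeInfoDb::Seqinfo(c("1", "2"), seqlengths = c(10000, 8000))
    genes <- GenomicRanges::GRanges(
        c("1", "1", "2"),
        IRanges::IRanges(c(500, 2000, 1000), width = c(100, 100, 100)),
        gene_id = c("mir-a", "mir-b", "mir-c"))
    cnvs <- GenomicRanges::GRanges(
        c("1", "1", "2"),
        IRanges::IRanges(c(400, 1500, 7000), c(1400, 2600, 7999)),
        cnv_type = c("Loss", "Loss", "Gain"))
    MirCnvDataset(gnm, genes, cnvs)
}
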