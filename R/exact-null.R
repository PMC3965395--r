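#' @include AllClasses.R
NULL

## Step function giving, for a CNV of length L placed at start s on a
## chromosome of length G, the number of genes it hits. Each gene maps to
## a window of start positions producing a hit:
##   any overlap : s in [gene_start - L + 1, gene_end]
##   containment : s in [gene_end - L + 1, gene_start]  (empty if the
##                 gene is longer than the CNV)
## clipped to the legal placements {1, ..., G - L + 1}. Returned as event
## breakpoints `pos` with cumulative values `val`; the count at start s is
## val[findInterval(s, pos)] (0 before the first breakpoint).
.hitStepFun <- function(L, geneStarts, geneEnds, G,
        overlapMode = c("any", "containment")) {
    overlapMode <- match.arg(overlapMode)
    S <- G - L + 1
    if (overlapMode == "any") {
        a <- pmax(1, geneStarts - L + 1)
        b <- pmin(S, geneEnds)
    } else {
        a <- pmax(1, geneEnds - L + 1)
        b <- pmin(S, geneStarts)
    }
    keep <- a <= b
    a <- a[keep]; b <- b[keep]
    if (length(a) == 0L)
        return(list(pos = numeric(0), val = numeric(0), S = S))
    pos <- c(a, b + 1)
    d <- c(rep(1, length(a)), rep(-1, length(b)))
    dsum <- rowsum(d, pos)              # grouped by sorted unique position
    upos <- as.numeric(rownames(dsum))
    list(pos = upos, val = cumsum(dsum[, 1L]), S = S)
}

.evalStepFun <- function(sf, s) {
    c(0, sf$val)[findInterval(s, sf$pos) + 1L]
}

## Sparse pmf of the per-CNV hit count derived from the step function:
## weight each constant segment of start positions by its width.
.stepFunPmf <- function(sf) {
    if (length(sf$pos) == 0L)
        return(c(`0` = 1))
    knots <- sort(unique(c(1, sf$pos[sf$pos <= sf$S], sf$S + 1)))
    vals <- .evalStepFun(sf, knots[-length(knots)])
    w <- diff(knots)
    p <- rowsum(w, vals)[, 1L] / sf$S
    p[p > 0]
}

#' Exact hit-count distribution for a single CNV
#'
#' The probability mass function of the number of miRNA genes overlapped
#' by one CNV of length `L` placed uniformly at random on a chromosome of
#' length `G` (start drawn uniformly from the `G - L + 1` placements that
#' keep the CNV wholly inside the chromosome). Two interchangeable
#' implementations are provided: an event-point sweep over
#' gene-boundary-shifted breakpoints (default, O(genes log genes)) and
#' direct enumeration of every legal start (for small `G`; used as a
#' cross-check).
#'
#' @param L CNV length in bp (`1 <= L <= G`).
#' @param genes A [GRanges] or [IRanges] of gene loci on the chromosome.
#' @param G Chromosome length in bp.
#' @param overlapMode `"any"` or `"containment"`.
#' @param method `"sweep"` or `"enumerate"`.
#' @return Named numeric vector: names are hit counts, values their
#'   probabilities (summing to 1).
#' @examples
#' exactHitDistribution(3, IRanges::IRanges(4, 5), 10)
#' # starts 2..5 of the 8 legal ones overlap: {0: 0.5, 1: 0.5}
#' @export
exactHitDistribution <- function(L, genes, G,
        overlapMode = c("any", "containment"),
        method = c("sweep", "enumerate")) {
    overlapMode <- match.arg(overlapMode)
    method <- match.arg(method)
    if (L < 1 || L > G)
        stop(sprintf("CNV length %g outside [1, G = %g]", L, G),
            call. = FALSE)
    gs <- as.numeric(start(genes))
    ge <- as.numeric(end(genes))
    if (method == "sweep") {
        sf <- .hitStepFun(L, gs, ge, G, overlapMode)
        return(.stepFunPmf(sf))
    }
    S <- G - L + 1
    if (S > 1e6)
        stop("enumeration only supported for G - L + 1 <= 1e6",
            call. = FALSE)
    s <- seq_len(S)
    e <- s + L - 1
    cnt <- numeric(S)
    for (j in seq_along(gs)) {
        hit <- if (overlapMode == "any") s <= ge[j] & e >= gs[j]
            else s <= gs[j] & e >= ge[j]
        cnt <- cnt + hit
    }
    tb <- table(cnt) / S
    p <- as.numeric(tb)
    names(p) <- names(tb)
    p
}

#' Convolve independent hit-count distributions
#'
#' Distribution of the total hits statistic over several CNVs placed
#' independently: the convolution of their per-CNV pmfs, kept sparse
#' (support to probability).
#'
#' @param pmfs A list of named numeric pmfs as returned by
#'   [exactHitDistribution()]; each must sum to 1 within `1e-12`.
#' @return Named numeric pmf of the sum; for an empty list, a point mass
#'   at 0.
#' @examples
#' b <- c(`0` = 0.5, `1` = 0.5)
#' convolvePmfs(list(b, b))  # {0: 0.25, 1: 0.5, 2: 0.25}
#' @export
convolvePmfs <- function(pmfs) {
    acc <- c(`0` = 1)
    for (i in seq_along(pmfs)) {
        q <- pmfs[[i]]
        if (abs(sum(q) - 1) > 1e-12)
            stop(sprintf("pmf %d does not sum to 1", i), call. = FALSE)
        sup <- outer(as.numeric(names(acc)), as.numeric(names(q)), `+`)
        pr <- outer(unname(acc), unname(q))
        agg <- rowsum(as.vector(pr), as.vector(sup))
        acc <- agg[, 1L]
        names(acc) <- rownames(agg)
    }
    acc
}

#' Exact null distribution of the total hits statistic
#'
#' Analytic counterpart of [simulateNull()]: the exact distribution of
#' the total number of gene hits when every CNV keeps its length and is
#' placed independently and uniformly at random within the chromosome.
#' Valid precisely because placements are independent (simulated CNVs may
#' overlap one another).
#'
#' @param genes A [GRanges] or [IRanges] of gene loci on the chromosome.
#' @param cnvLengths Numeric vector of CNV lengths in bp.
#' @param G Chromosome length in bp.
#' @param overlapMode `"any"` or `"containment"`.
#' @param chrom,cnvType Optional labels stored in the result.
#' @return A [NullDistribution-class] with `source = "exact"`.
#' @export
exactNullDistribution <- function(genes, cnvLengths, G,
        overlapMode = c("any", "containment"),
        chrom = NA_character_, cnvType = NA_character_) {
    overlapMode <- match.arg(overlapMode)
    pmfs <- lapply(cnvLengths, exactHitDistribution, genes = genes, G = G,
        overlapMode = overlapMode)
    .NullDistribution(convolvePmfs(pmfs), source = "exact",
        chrom = chrom, cnvType = cnvType)
}
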