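#' @include AllClasses.R
NULL

#' Locus lengths under the 1-based inclusive convention
#'
#' The genomic size of each locus, `end - start + 1` bp. This matches the
#' miRBase "Size (bp)" convention for hairpin loci (e.g. hsa-mir-137 at
#' GRCh37 1:98511626-98511727 has size 102).
#'
#' @param x A [GRanges] or [IRanges].
#' @return Integer vector of lengths in bp.
#' @examples
#' geneLengths(IRanges::IRanges(98511626, 98511727))  # 102
#' @export
geneLengths <- function(x) {
    end(x) - start(x) + 1L
}

#' Union length of a set of intervals
#'
#' Total number of base positions covered by at least one interval,
#' counting bases shared by overlapping intervals once only. Computed by
#' sort-and-sweep merging of closed intervals.
#'
#' @param x A [GRanges] (all on one chromosome, and of one `cnv_type` if
#'   that metadata column is present) or an [IRanges].
#' @return Union length in bp (numeric scalar).
#' @examples
#' unionLength(IRanges::IRanges(c(100, 150), c(199, 320)))  # 221
#' @export
unionLength <- function(x) {
    if (length(x) == 0L)
        return(0)
    if (is(x, "GRanges")) {
        if (length(unique(as.character(seqnames(x)))) > 1L)
            stop("unionLength expects intervals on a single chromosome",
                call. = FALSE)
        if ("cnv_type" %in% colnames(mcols(x)) &&
            length(unique(mcols(x)$cnv_type)) > 1L)
            stop("unionLength expects CNVs of a single type", call. = FALSE)
    }
    s <- as.numeric(start(x))
    e <- as.numeric(end(x))
    o <- order(s, e)
    s <- s[o]
    e <- cummax(e[o])
    ## a merged block starts wherever the next start exceeds the running
    ## maximum end (closed intervals: touching blocks may stay split,
    ## the summed widths are identical)
    newBlock <- c(TRUE, s[-1L] > e[-length(e)] )
    grp <- cumsum(newBlock)
    sum(tapply(e, grp, max) - tapply(s, grp, min) + 1)
}

## Pairwise overlap indicator matrix, CNVs in rows, genes in columns.
## Closed-interval intersection ("any") or full gene containment.
.overlapMatrix <- function(cnvs, genes, overlapMode = c("any", "containment")) {
    overlapMode <- match.arg(overlapMode)
    cs <- start(cnvs); ce <- end(cnvs)
    gs <- start(genes); ge <- end(genes)
    if (overlapMode == "any")
        outer(cs, ge, `<=`) & outer(ce, gs, `>=`)
    else
        outer(cs, gs, `<=`) & outer(ce, ge, `>=`)
}

#' Does a CNV overlap a miRNA gene?
#'
#' Closed-interval test: under `overlapMode = "any"` the pair overlaps iff
#' they share at least one base (`cnv_start <= gene_end` and
#' `cnv_end >= gene_start`); adjacency is not overlap. Under
#' `"containment"` the CNV must contain the whole gene. Strand is ignored
#' (CNVs are unstranded events).
#'
#' @param cnv,gene Parallel [GRanges] (recycled if one has length 1). All
#'   compared pairs must lie on the same chromosome.
#' @param overlapMode `"any"` (default) or `"containment"`.
#' @return Logical vector.
#' @examples
#' cnv <- GenomicRanges::GRanges("1", IRanges::IRanges(100, 5000))
#' gene <- GenomicRanges::GRanges("1", IRanges::IRanges(4990, 5080))
#' cnvOverlapsGene(cnv, gene)        # TRUE (11 shared bases)
#' @export
cnvOverlapsGene <- function(cnv, gene, overlapMode = c("any", "containment")) {
    overlapMode <- match.arg(overlapMode)
    n <- max(length(cnv), length(gene))
    cnv <- rep(cnv, length.out = n)
    gene <- rep(gene, length.out = n)
    if (!all(as.character(seqnames(cnv)) == as.character(seqnames(gene))))
        stop("cnvOverlapsGene: compared pairs lie on different chromosomes",
            call. = FALSE)
    if (overlapMode == "any")
        start(cnv) <= end(gene) & end(cnv) >= start(gene)
    else
        start(cnv) <= start(gene) & end(cnv) >= end(gene)
}

#' Count miRNA-gene hits inside a set of CNVs
#'
#' The "hits" statistic: the sum over CNVs of the number of miRNA genes
#' each overlaps, so a gene overlapped by two distinct CNVs contributes
#' two hits. `unique` is the number of distinct genes overlapped by at
#' least one CNV, hence `unique <= hits`.
#'
#' @param cnvs A [GRanges] of CNVs on one chromosome (and of one type if
#'   `cnv_type` is present); typically deduplicated calls.
#' @param genes A [GRanges] of miRNA genes; genes on other chromosomes
#'   are ignored.
#' @param overlapMode `"any"` or `"containment"` (see
#'   [cnvOverlapsGene()]).
#' @return Named numeric vector `c(hits = , unique = )`.
#' @examples
#' genes <- GenomicRanges::GRanges("1", IRanges::IRanges(500, 599))
#' cnvs <- GenomicRanges::GRanges("1",
#'     IRanges::IRanges(c(400, 550), c(1400, 2000)))
#' countHits(cnvs, genes)  # 2 hits, 1 unique
#' @export
countHits <- function(cnvs, genes, overlapMode = c("any", "containment")) {
    overlapMode <- match.arg(overlapMode)
    if (length(cnvs) == 0L)
        return(c(hits = 0, unique = 0))
    chrom <- unique(as.character(seqnames(cnvs)))
    if (length(chrom) > 1L)
        stop("countHits expects CNVs on a single chromosome", call. = FALSE)
    if ("cnv_type" %in% colnames(mcols(cnvs)) &&
        length(unique(mcols(cnvs)$cnv_type)) > 1L)
        stop("countHits expects CNVs of a single type", call. = FALSE)
    genes <- genes[as.character(seqnames(genes)) == chrom]
    if (length(genes) == 0L)
        return(c(hits = 0, unique = 0))
    m <- .overlapMatrix(cnvs, genes, overlapMode)
    c(hits = sum(m), unique = sum(colSums(m) > 0L))
}

#' Per-(chromosome, CNV type) interval summary
#'
#' For every chromosome in the genome model and each CNV type (Gain,
#' Loss), computes the summed miRNA gene length `L1`, the union length of
#' the CNVs `L2` (overlapping CNV regions counted once), the fractional
#' ratios `R1 = L1 / G` and `R2 = L2 / G` where `G` is the chromosome
#' length, and the overlap counts `hits` and `unique` (see
#' [countHits()]). Combinations without any CNV are emitted with `NA` in
#' the CNV-dependent columns, preserving "no data" semantics.
#'
#' @param x A [MirCnvDataset-class].
#' @param overlapMode `"any"` or `"containment"`.
#' @return A [DataFrame] with columns `chrom`, `cnv_type`, `n_mirna`,
#'   `n_cnvs`, `L1`, `L2`, `R1`, `R2`, `hits`, `unique`; `overlapMode` is
#'   stored in its `metadata()`.
#' @export
summarizeCnvMirna <- function(x, overlapMode = c("any", "containment")) {
    stopifnot(is(x, "MirCnvDataset"))
    overlapMode <- match.arg(overlapMode)
    gnm <- seqinfo(x)
    genes <- mirnaGenes(x)
    cnvs <- cnvCalls(x)
    chroms <- seqnames(gnm)
    rows <- expand.grid(cnv_type = .CNV_TYPES, chrom = chroms,
        stringsAsFactors = FALSE)[, 2:1]
    n <- nrow(rows)
    out <- DataFrame(
        chrom = rows$chrom, cnv_type = rows$cnv_type,
        n_mirna = integer(n), n_cnvs = integer(n),
        L1 = numeric(n), L2 = rep(NA_real_, n),
        R1 = numeric(n), R2 = rep(NA_real_, n),
        hits = rep(NA_real_, n), unique = rep(NA_real_, n))
    for (i in seq_len(n)) {
        chrom <- rows$chrom[i]
        type <- rows$cnv_type[i]
        G <- as.numeric(seqlengths(gnm)[[chrom]])
        g <- genes[as.character(seqnames(genes)) == chrom]
        cc <- cnvs[as.character(seqnames(cnvs)) == chrom &
            mcols(cnvs)$cnv_type == type]
        out$n_mirna[i] <- length(g)
        out$n_cnvs[i] <- length(cc)
        out$L1[i] <- sum(as.numeric(geneLengths(g)))
        out$R1[i] <- out$L1[i] / G
        if (length(cc) > 0L) {
            out$L2[i] <- unionLength(cc)
            out$R2[i] <- out$L2[i] / G
            h <- countHits(cc, g, overlapMode)
            out$hits[i] <- h[["hits"]]
            out$unique[i] <- h[["unique"]]
        }
    }
    metadata(out) <- list(overlapMode = overlapMode)
    out
}
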