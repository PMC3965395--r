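#' @include cnvMir-package.R
NULL

.CNV_TYPES <- c("Gain", "Loss")

#' Container for one miRNA/CNV analysis
#'
#' `MirCnvDataset` bundles a genome model ([Seqinfo]: chromosome names and
#' lengths), the miRNA gene annotation and the CNV calls for one analysis.
#' Coordinates are 1-based inclusive on both ends (GRCh37 convention, the
#' native [GRanges] convention); the locus size is therefore
#' `end - start + 1`. Validity checks that every range lies on a modelled
#' chromosome and within its bounds, that gene identifiers are unique, and
#' that every CNV is typed as `"Gain"` or `"Loss"`.
#'
#' @slot genome A [Seqinfo] with one entry per chromosome.
#' @slot mirna A [GRanges] of miRNA gene loci with a `gene_id` metadata
#'   column.
#' @slot cnv A [GRanges] of CNV calls with metadata columns `cnv_type`
#'   (`"Gain"`/`"Loss"`), `patients` (a [CharacterList] of patient ids per
#'   deduplicated call) and `source` (`"case"` or `"population"`).
#' @slot metadata A list of free-form provenance (e.g. generator
#'   parameters).
#'
#' @seealso [readChromSizes()], [readMirnaAnnotation()], [readCnvTable()],
#'   [simulateDataset()], [summarizeCnvMirna()], [testEnrichment()]
#' @name MirCnvDataset-class
#' @exportClass MirCnvDataset
setClass("MirCnvDataset",
    slots = c(
        genome = "Seqinfo",
        mirna = "GRanges",
        cnv = "GRanges",
        metadata = "list"
    )
)

.validMirCnvDataset <- function(object) {
    msg <- character()
    gnm <- object@genome
    chroms <- seqnames(gnm)
    for (what in c("mirna", "cnv")) {
        gr <- slot(object, what)
        bad <- setdiff(as.character(unique(seqnames(gr))), chroms)
        if (length(bad) > 0L) {
            msg <- c(msg, sprintf(
                "%s records on chromosomes absent from the genome model: %s",
                what, paste(bad, collapse = ", ")))
            next
        }
        if (length(gr) > 0L) {
            lens <- seqlengths(gnm)[as.character(seqnames(gr))]
            if (any(end(gr) > lens, na.rm = TRUE))
                msg <- c(msg, sprintf(
                    "%s records extend beyond chromosome bounds", what))
            if (any(width(gr) < 1L))
                msg <- c(msg, sprintf("%s records with end < start", what))
        }
    }
    if (!"gene_id" %in% colnames(mcols(object@mirna))) {
        msg <- c(msg, "mirna must carry a 'gene_id' metadata column")
    } else {
        ids <- mcols(object@mirna)$gene_id
        if (anyDuplicated(ids))
            msg <- c(msg, sprintf("duplicated gene_id: %s",
                paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
    if (!"cnv_type" %in% colnames(mcols(object@cnv))) {
        msg <- c(msg, "cnv must carry a 'cnv_type' metadata column")
    } else if (!all(mcols(object@cnv)$cnv_type %in% .CNV_TYPES)) {
        msg <- c(msg, "cnv_type values must be 'Gain' or 'Loss'")
    }
    if (length(msg)) msg else TRUE
}

setValidity("MirCnvDataset", .validMirCnvDataset)

#' Construct a MirCnvDataset
#'
#' @param genome A [Seqinfo] (see [readChromSizes()]) giving chromosome
#'   names and lengths.
#' @param mirna A [GRanges] of miRNA gene loci with a `gene_id` metadata
#'   column (see [readMirnaAnnotation()]).
#' @param cnv A [GRanges] of CNV calls with a `cnv_type` metadata column
#'   (see [readCnvTable()]).
#' @param metadata Optional list of provenance information.
#'
#' @return A validated [MirCnvDataset-class] object whose ranges carry the
#'   genome's [Seqinfo].
#'
#' @examples
#' gnm <- GenomeInfoDb::Seqinfo("1", seqlengths = 10000)
#' genes <- GenomicRanges::GRanges("1", IRanges::IRanges(500, 599),
#'     gene_id = "mir-a")
#' cnvs <- GenomicRanges::GRanges("1", IRanges::IRanges(400, 1400),
#'     cnv_type = "Loss")
#' MirCnvDataset(gnm, genes, cnvs)
#' @export
MirCnvDataset <- function(genome, mirna, cnv, metadata = list()) {
    stopifnot(is(genome, "Seqinfo"), is(mirna, "GRanges"), is(cnv, "GRanges"))
    mirna <- .harmonizeSeqinfo(mirna, genome, "miRNA gene")
    cnv <- .harmonizeSeqinfo(cnv, genome, "CNV")
    if (!"patients" %in% colnames(mcols(cnv)))
        mcols(cnv)$patients <- as(as.list(rep(NA_character_, length(cnv))),
            "CharacterList")
    if (!"source" %in% colnames(mcols(cnv)))
        mcols(cnv)$source <- rep("case", length(cnv))
    new("MirCnvDataset", genome = genome, mirna = mirna, cnv = cnv,
        metadata = metadata)
}

## Re-level a GRanges onto the genome model, failing with the offending
## records rather than GRanges' generic seqlevel error.
.harmonizeSeqinfo <- function(gr, genome, what) {
    bad <- setdiff(as.character(unique(seqnames(gr))), seqnames(genome))
    if (length(bad) > 0L) {
        ids <- if ("gene_id" %in% colnames(mcols(gr)))
            mcols(gr)$gene_id[as.character(seqnames(gr)) %in% bad]
        else sprintf("%s:%d-%d", as.character(seqnames(gr))[
            as.character(seqnames(gr)) %in% bad],
            start(gr)[as.character(seqnames(gr)) %in% bad],
            end(gr)[as.character(seqnames(gr)) %in% bad])
        stop(sprintf(
            "%s records on chromosomes absent from the genome model (%s): %s",
            what, paste(bad, collapse = ", "),
            paste(head(ids, 10L), collapse = ", ")), call. = FALSE)
    }
    lens <- seqlengths(genome)[as.character(seqnames(gr))]
    oob <- which(end(gr) > lens)
    if (length(oob) > 0L)
        stop(sprintf(
            "%s records extend beyond chromosome bounds: %s",
            what, paste(sprintf("%s:%d-%d",
                as.character(seqnames(gr))[oob], start(gr)[oob],
                end(gr)[oob])[seq_len(min(10L, length(oob)))],
                collapse = ", ")), call. = FALSE)
    out <- GRanges(
        seqnames = factor(as.character(seqnames(gr)),
            levels = seqnames(genome)),
        ranges = ranges(gr), strand = strand(gr), seqinfo = genome)
    mcols(out) <- mcols(gr)
    out
}

#' @describeIn MirCnvDataset-class The miRNA gene annotation.
#' @param x,object A `MirCnvDataset`.
#' @export
mirnaGenes <- function(x) {
    stopifnot(is(x, "MirCnvDataset"))
    x@mirna
}

#' @describeIn MirCnvDataset-class The CNV calls.
#' @export
cnvCalls <- function(x) {
    stopifnot(is(x, "MirCnvDataset"))
    x@cnv
}

#' @describeIn MirCnvDataset-class The genome model ([Seqinfo]).
#' @export
setMethod("seqinfo", "MirCnvDataset", function(x) x@genome)

setMethod("show", "MirCnvDataset", function(object) {
    cat(sprintf(
        "MirCnvDataset: %d chromosome(s), %d miRNA gene(s), %d CNV call(s)\n",
        length(seqnames(object@genome)), length(object@mirna),
        length(object@cnv)))
    tp <- table(factor(mcols(object@cnv)$cnv_type, levels = .CNV_TYPES))
    cat(sprintf("  CNV types: %d Gain, %d Loss\n", tp[["Gain"]], tp[["Loss"]]))
    invisible(NULL)
})

#' Null distribution of the hits statistic
#'
#' The distribution of the total overlap count ("hits") between miRNA
#' genes and CNVs re-placed uniformly at random within one chromosome,
#' either tallied over Monte Carlo realizations (`source = "monte_carlo"`,
#' `counts` holds realization counts summing to `nRealizations`) or
#' derived analytically by convolution (`source = "exact"`, `counts`
#' holds probabilities summing to 1).
#'
#' @slot chrom,cnvType Labels identifying the tested combination (may be
#'   `NA` for free-standing distributions).
#' @slot counts Named numeric vector; names are hit counts (non-negative
#'   integers), values are realization counts or probabilities.
#' @slot nRealizations Number of Monte Carlo realizations (`NA` for exact
#'   distributions).
#' @slot seed The RNG seed used, if one was set (`NA` otherwise).
#' @slot source `"monte_carlo"` or `"exact"`.
#'
#' @seealso [simulateNull()], [exactNullDistribution()],
#'   [empiricalPvalue()]
#' @name NullDistribution-class
#' @exportClass NullDistribution
setClass("NullDistribution",
    slots = c(
        chrom = "character",
        cnvType = "character",
        counts = "numeric",
        nRealizations = "numeric",
        seed = "numeric",
        source = "character"
    )
)

setValidity("NullDistribution", function(object) {
    msg <- character()
    if (!object@source %in% c("monte_carlo", "exact"))
        msg <- c(msg, "source must be 'monte_carlo' or 'exact'")
    sup <- suppressWarnings(as.numeric(names(object@counts)))
    if (length(object@counts) == 0L)
        msg <- c(msg, "counts must be non-empty")
    else if (anyNA(sup) || any(sup < 0) || any(sup != round(sup)))
        msg <- c(msg, "support must be non-negative integers")
    if (any(object@counts < 0))
        msg <- c(msg, "counts must be non-negative")
    if (identical(object@source, "monte_carlo")) {
        if (is.na(object@nRealizations) ||
            abs(sum(object@counts) - object@nRealizations) > 1e-8)
            msg <- c(msg, "counts must sum to nRealizations")
    } else if (abs(sum(object@counts) - 1) > 1e-12) {
        msg <- c(msg, "exact probabilities must sum to 1 within 1e-12")
    }
    if (length(msg)) msg else TRUE
})

.NullDistribution <- function(counts, source, nRealizations = NA_real_,
        seed = NA_real_, chrom = NA_character_, cnvType = NA_character_) {
    sup <- as.numeric(names(counts))
    o <- order(sup)
    new("NullDistribution", chrom = chrom, cnvType = cnvType,
        counts = counts[o], nRealizations = nRealizations,
        seed = seed, source = source)
}

#' @describeIn NullDistribution-class Named vector of realization counts
#'   (or probabilities, for exact nulls) indexed by hit count.
#' @param x,object A `NullDistribution`.
#' @export
nullCounts <- function(x) {
    stopifnot(is(x, "NullDistribution"))
    x@counts
}

#' @describeIn NullDistribution-class `"monte_carlo"` or `"exact"`.
#' @export
nullSource <- function(x) {
    stopifnot(is(x, "NullDistribution"))
    x@source
}

#' @describeIn NullDistribution-class The mean of the null hit-count
#'   distribution.
#' @export
nullMean <- function(x) {
    stopifnot(is(x, "NullDistribution"))
    sup <- as.numeric(names(x@counts))
    sum(sup * x@counts) / sum(x@counts)
}

setMethod("show", "NullDistribution", function(object) {
    lab <- if (is.na(object@chrom)) "" else
        sprintf(" [chr%s %s]", object@chrom, object@cnvType)
    cat(sprintf("NullDistribution (%s)%s\n", object@source, lab))
    if (identical(object@source, "monte_carlo"))
        cat(sprintf("  %g realizations%s\n", object@nRealizations,
            if (is.na(object@seed)) "" else sprintf(", seed %g", object@seed)))
    sup <- as.numeric(names(object@counts))
    cat(sprintf("  hit-count support %d..%d, mean %.4g\n",
        min(sup), max(sup), nullMean(object)))
    invisible(NULL)
})

#' Per-chromosome enrichment test results
#'
#' A [DataFrame] subclass holding one row per (chromosome, CNV type)
#' combination with columns `chrom`, `cnv_type`, `n_cnvs`, `unique`,
#' `hits`, `p_raw` (empirical upper-tail p-value), `p_fdr`
#' (Benjamini-Hochberg adjusted) and `significant` (`p_fdr < alpha`).
#' Combinations without CNVs carry `NA` (the tabular writers render them
#' as `"N/A"`). Analysis parameters (alpha, realizations, seed, overlap
#' mode, FDR family) live in `metadata()`.
#'
#' @seealso [testEnrichment()], [selectSignificant()]
#' @name EnrichmentResults-class
#' @exportClass EnrichmentResults
setClass("EnrichmentResults", contains = "DFrame")

setMethod("show", "EnrichmentResults", function(object) {
    md <- metadata(object)
    cat(sprintf(
        "EnrichmentResults: %d chromosome/type combinations (alpha = %g, %s)\n",
        nrow(object), md$alpha,
        if (isTRUE(md$exact)) "exact null"
        else sprintf("%g realizations", md$nRealizations)))
    nsig <- sum(object$significant, na.rm = TRUE)
    cat(sprintf("  significant at FDR < %g: %d\n", md$alpha, nsig))
    callNextMethod()
})

#' Correlation between hit counts and CNV coverage
#'
#' Pearson correlation and least-squares fit of per-chromosome miRNA hit
#' counts on the fractional CNV coverage R2 (union CNV length divided by
#' chromosome length), computed separately per CNV type over chromosomes
#' with data.
#'
#' @slot cnvType `"Gain"` or `"Loss"`.
#' @slot nPoints Number of chromosomes used.
#' @slot r Pearson correlation coefficient.
#' @slot slope,intercept Least-squares fit of hits on R2.
#'
#' @seealso [correlateHitsCoverage()]
#' @name CorrelationResult-class
#' @exportClass CorrelationResult
setClass("CorrelationResult",
    slots = c(cnvType = "character", nPoints = "integer", r = "numeric",
        slope = "numeric", intercept = "numeric")
)

setMethod("show", "CorrelationResult", function(object) {
    cat(sprintf(
        "CorrelationResult (%s): r = %.5f over %d chromosomes\n",
        object@cnvType, object@r, object@nPoints))
    cat(sprintf("  hits ~ %.4g + %.4g * R2\n", object@intercept,
        object@slope))
    invisible(NULL)
})
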