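#' @include randomization.R
NULL

#' Benjamini-Hochberg step-up adjustment
#'
#' FDR-adjusted p-values by the Benjamini-Hochberg step-up procedure:
#' with `m` tests sorted ascending, the adjusted value at rank `i` is
#' `min over j >= i of p_(j) * m / j`, capped at 1 and returned in input
#' order. Delegates to [stats::p.adjust()] after validating the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (no `NA`s).
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
bhAdjust <- function(p) {
    if (!is.numeric(p))
        stop("p-values must be numeric", call. = FALSE)
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    p.adjust(p, method = "BH")
}

#' Chromosome-wide enrichment test with FDR control
#'
#' Runs the full two-stage analysis on a dataset: per (chromosome, CNV
#' type) combination with at least one CNV, the observed hits statistic
#' is computed ([summarizeCnvMirna()]) and compared against the null of
#' uniformly re-placed CNVs ([simulateNull()], or
#' [exactNullDistribution()] when `exact = TRUE`), giving an empirical
#' upper-tail p-value. P-values are then Benjamini-Hochberg adjusted --
#' by default separately within the Gain family and within the Loss
#' family over combinations that have data (`fdrFamily = "per-type"`), or
#' across both at once (`"joint"`). A combination is flagged significant
#' when `p_fdr < alpha` (strict).
#'
#' @param x A [MirCnvDataset-class].
#' @param nRealizations Monte Carlo realizations per combination
#'   (default `1e6`).
#' @param seed Optional seed fixing the whole run.
#' @param alpha FDR significance level (default `0.05`).
#' @param overlapMode `"any"` or `"containment"`.
#' @param fdrFamily `"per-type"` (default) or `"joint"`.
#' @param exact Use the exact convolution null instead of sampling.
#' @param correction Passed to [empiricalPvalue()].
#' @return An [EnrichmentResults-class]; the fitted null distributions
#'   are kept in `metadata()$nulls`.
#' @examples
#' ds <- simulateDataset(nCnvs = 4, enrichment = 1, seed = 7)
#' res <- testEnrichment(ds, nRealizations = 2000, seed = 1)
#' selectSignificant(res)
#' @export
testEnrichment <- function(x, nRealizations = 1e6, seed = NULL,
        alpha = 0.05, overlapMode = c("any", "containment"),
        fdrFamily = c("per-type", "joint"), exact = FALSE,
        correction = c("none", "add-one")) {
    stopifnot(is(x, "MirCnvDataset"))
    overlapMode <- match.arg(overlapMode)
    fdrFamily <- match.arg(fdrFamily)
    correction <- match.arg(correction)
    summ <- summarizeCnvMirna(x, overlapMode)
    if (!is.null(seed))
        set.seed(seed)
    genes <- mirnaGenes(x)
    cnvs <- cnvCalls(x)
    lens <- seqlengths(seqinfo(x))
    p_raw <- rep(NA_real_, nrow(summ))
    nulls <- vector("list", nrow(summ))
    for (i in seq_len(nrow(summ))) {
        if (summ$n_cnvs[i] == 0L)
            next
        chrom <- summ$chrom[i]
        type <- summ$cnv_type[i]
        g <- genes[as.character(seqnames(genes)) == chrom]
        cl <- geneLengths(cnvs[as.character(seqnames(cnvs)) == chrom &
            mcols(cnvs)$cnv_type == type])
        nd <- if (exact)
            exactNullDistribution(g, cl, as.numeric(lens[[chrom]]),
                overlapMode, chrom = chrom, cnvType = type)
        else
            simulateNull(g, cl, as.numeric(lens[[chrom]]),
                nRealizations = nRealizations, seed = NULL,
                overlapMode = overlapMode, chrom = chrom, cnvType = type)
        nulls[[i]] <- nd
        p_raw[i] <- empiricalPvalue(nd, summ$hits[i], correction)
    }
    p_fdr <- rep(NA_real_, length(p_raw))
    tested <- !is.na(p_raw)
    if (fdrFamily == "per-type") {
        for (type in .CNV_TYPES) {
            sel <- tested & summ$cnv_type == type
            if (any(sel))
                p_fdr[sel] <- bhAdjust(p_raw[sel])
        }
    } else if (any(tested)) {
        p_fdr[tested] <- bhAdjust(p_raw[tested])
    }
    res <- new("EnrichmentResults", DataFrame(
        chrom = summ$chrom, cnv_type = summ$cnv_type,
        n_cnvs = summ$n_cnvs, unique = summ$unique, hits = summ$hits,
        p_raw = p_raw, p_fdr = p_fdr,
        significant = ifelse(is.na(p_fdr), NA, p_fdr < alpha)))
    metadata(res) <- list(alpha = alpha, nRealizations = nRealizations,
        seed = seed, overlapMode = overlapMode, fdrFamily = fdrFamily,
        exact = exact, correction = correction, summary = summ,
        nulls = nulls)
    res
}

#' Select significant chromosome/type combinations
#'
#' Rows with an FDR-adjusted p-value strictly below `alpha`; rows without
#' data (`NA`) are never selected.
#'
#' @param results An [EnrichmentResults-class] (or any table with a
#'   `p_fdr` column).
#' @param alpha Significance level; defaults to the alpha stored in the
#'   results' `metadata()`, or 0.05.
#' @return The selected subset, same class as the input.
#' @export
selectSignificant <- function(results, alpha = NULL) {
    if (is.null(alpha))
        alpha <- metadata(results)$alpha
    if (is.null(alpha))
        alpha <- 0.05
    keep <- !is.na(results$p_fdr) & results$p_fdr < alpha
    results[keep, , drop = FALSE]
}

#' Correlate hit counts with fractional CNV coverage
#'
#' Pearson correlation between the per-chromosome hits statistic and the
#' fractional CNV coverage `R2`, together with the least-squares fit of
#' hits on R2, over chromosomes with data for the given CNV type
#' (combinations without CNVs are excluded).
#'
#' @param summaries A per-(chromosome, type) summary as returned by
#'   [summarizeCnvMirna()] (any table with columns `cnv_type`, `R2` and
#'   `hits` works).
#' @param cnvType `"Gain"` or `"Loss"`.
#' @return A [CorrelationResult-class].
#' @export
correlateHitsCoverage <- function(summaries, cnvType = c("Gain", "Loss")) {
    cnvType <- match.arg(cnvType)
    sel <- summaries$cnv_type == cnvType & !is.na(summaries$R2) &
        !is.na(summaries$hits)
    r2 <- as.numeric(summaries$R2[sel])
    hits <- as.numeric(summaries$hits[sel])
    if (length(r2) < 3L)
        stop(sprintf(
            "correlation requires >= 3 chromosomes with data (got %d)",
            length(r2)), call. = FALSE)
    if (stats::var(r2) == 0 || stats::var(hits) == 0)
        stop("correlation undefined: zero variance in R2 or hits",
            call. = FALSE)
    fit <- coef(lm(hits ~ r2))
    new("CorrelationResult", cnvType = cnvType, nPoints = length(r2),
        r = stats::cor(r2, hits), slope = unname(fit[2L]),
        intercept = unname(fit[1L]))
}

#' Candidate miRNA genes from significant combinations
#'
#' The union of distinct miRNA genes overlapped by at least one CNV on a
#' significant (chromosome, CNV type) combination. Each candidate is
#' annotated with the CNV types implicating it and the number of distinct
#' patients whose CNVs overlap it.
#'
#' @param x The [MirCnvDataset-class] that produced `results`.
#' @param results An [EnrichmentResults-class] from [testEnrichment()].
#' @param alpha Passed to [selectSignificant()].
#' @param overlapMode `"any"` or `"containment"`; defaults to the mode
#'   recorded in `results`.
#' @return A [GRanges] of candidate genes with metadata columns
#'   `gene_id`, `types` and `n_patients`.
#' @export
enrichedCandidates <- function(x, results, alpha = NULL,
        overlapMode = NULL) {
    stopifnot(is(x, "MirCnvDataset"))
    if (is.null(overlapMode))
        overlapMode <- metadata(results)$overlapMode
    if (is.null(overlapMode))
        overlapMode <- "any"
    sig <- selectSignificant(results, alpha)
    genes <- mirnaGenes(x)
    cnvs <- cnvCalls(x)
    hitIdx <- integer(0)
    types <- character(0)
    patients <- list()
    for (i in seq_len(nrow(sig))) {
        chrom <- sig$chrom[i]
        type <- sig$cnv_type[i]
        gIdx <- which(as.character(seqnames(genes)) == chrom)
        cc <- cnvs[as.character(seqnames(cnvs)) == chrom &
            mcols(cnvs)$cnv_type == type]
        if (length(gIdx) == 0L || length(cc) == 0L)
            next
        m <- .overlapMatrix(cc, genes[gIdx], overlapMode)
        hit <- colSums(m) > 0L
        for (k in which(hit)) {
            idx <- gIdx[k]
            pats <- unlist(mcols(cc)$patients[m[, k]])
            pos <- match(idx, hitIdx)
            if (is.na(pos)) {
                hitIdx <- c(hitIdx, idx)
                types <- c(types, type)
                patients <- c(patients, list(pats))
            } else {
                types[pos] <- paste(sort(unique(
                    c(strsplit(types[pos], "/")[[1L]], type))),
                    collapse = "/")
                patients[[pos]] <- c(patients[[pos]], pats)
            }
        }
    }
    out <- genes[hitIdx]
    mcols(out)$types <- types
    mcols(out)$n_patients <- vapply(patients,
        function(p) length(unique(p[!is.na(p)])), integer(1L))
    sort(out)
}

#' Flag candidates seen in population CNVs
#'
#' Annotates each candidate miRNA gene with whether it overlaps at least
#' one CNV from a population catalogue (DGV-style; Gains and Losses are
#' pooled). Candidates not seen in any population CNV are the
#' study-specific ones.
#'
#' @param candidates A [GRanges] of candidate genes (see
#'   [enrichedCandidates()]).
#' @param populationCnvs A [GRanges] of population CNVs (e.g. from
#'   [readCnvTable()] with `source = "population"`); may be empty.
#' @param overlapMode `"any"` or `"containment"` (same predicate as the
#'   enrichment analysis).
#' @return `candidates` with a logical `in_population` metadata column.
#' @export
populationFilter <- function(candidates, populationCnvs,
        overlapMode = c("any", "containment")) {
    overlapMode <- match.arg(overlapMode)
    inPop <- logical(length(candidates))
    if (length(populationCnvs) > 0L && length(candidates) > 0L) {
        for (i in seq_along(candidates)) {
            cc <- populationCnvs[as.character(seqnames(populationCnvs)) ==
                as.character(seqnames(candidates[i]))]
            if (length(cc) == 0L)
                next
            inPop[i] <- any(.overlapMatrix(cc, candidates[i], overlapMode))
        }
    }
    mcols(candidates)$in_population <- inPop
    candidates
}
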