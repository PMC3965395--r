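#' @include exact-null.R
NULL

#' Randomly re-place CNVs within a chromosome
#'
#' Draws one random placement for each CNV: the length is kept fixed and
#' the start is drawn uniformly from the `G - L + 1` positions that keep
#' the interval wholly inside the chromosome. Placements are mutually
#' independent, so simulated CNVs may overlap one another.
#'
#' Uses the current RNG stream; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param cnvLengths Numeric vector of CNV lengths in bp.
#' @param G Chromosome length in bp.
#' @return An [IRanges] of the placed intervals, parallel to
#'   `cnvLengths`.
#' @examples
#' set.seed(1)
#' placeRandom(c(3, 5), 10)
#' @export
placeRandom <- function(cnvLengths, G) {
    bad <- which(cnvLengths < 1 | cnvLengths > G)
    if (length(bad) > 0L)
        stop(sprintf(
            "CNV %d has length %g outside the chromosome (G = %g)",
            bad[1L], cnvLengths[bad[1L]], G), call. = FALSE)
    s <- vapply(G - cnvLengths + 1, function(S) sample.int(S, 1L), 1L)
    IRanges(start = s, width = cnvLengths)
}

#' Monte Carlo null distribution of the hits statistic
#'
#' Simulates the null hypothesis that CNVs occur anywhere in the
#' chromosome with uniform probability: in each realization every CNV of
#' one type keeps its length and is independently re-placed uniformly at
#' random, and the total hits statistic (same definition as
#' [countHits()]) is computed against the fixed gene annotation. The
#' hit-count histogram over all realizations is returned.
#'
#' Internally each CNV's hit count is evaluated through a precomputed
#' step function over gene-boundary-shifted breakpoints, so the cost per
#' realization is O(CNVs x log genes) rather than O(CNVs x genes).
#'
#' @param genes A [GRanges] or [IRanges] of gene loci on the chromosome.
#' @param cnvLengths Numeric vector of CNV lengths in bp (one CNV type at
#'   a time).
#' @param G Chromosome length in bp.
#' @param nRealizations Number of Monte Carlo realizations (default
#'   `1e6`).
#' @param seed Optional RNG seed, recorded in the result; when `NULL` the
#'   current RNG stream is used.
#' @param overlapMode `"any"` or `"containment"`.
#' @param chrom,cnvType Optional labels stored in the result.
#' @return A [NullDistribution-class] with `source = "monte_carlo"`.
#' @examples
#' genes <- IRanges::IRanges(c(2000, 7000), width = 100)
#' nd <- simulateNull(genes, c(500, 1500), 1e4, nRealizations = 1000,
#'     seed = 1)
#' empiricalPvalue(nd, 2)
#' @export
simulateNull <- function(genes, cnvLengths, G, nRealizations = 1e6,
        seed = NULL, overlapMode = c("any", "containment"),
        chrom = NA_character_, cnvType = NA_character_) {
    overlapMode <- match.arg(overlapMode)
    stopifnot(nRealizations >= 1)
    if (!is.null(seed))
        set.seed(seed)
    bad <- which(cnvLengths < 1 | cnvLengths > G)
    if (length(bad) > 0L)
        stop(sprintf(
            "CNV %d has length %g outside the chromosome (G = %g)",
            bad[1L], cnvLengths[bad[1L]], G), call. = FALSE)
    gs <- as.numeric(start(genes))
    ge <- as.numeric(end(genes))
    total <- numeric(nRealizations)
    for (L in cnvLengths) {
        sf <- .hitStepFun(L, gs, ge, G, overlapMode)
        s <- sample.int(sf$S, nRealizations, replace = TRUE)
        total <- total + .evalStepFun(sf, s)
    }
    tb <- table(total)
    counts <- as.numeric(tb)
    names(counts) <- names(tb)
    .NullDistribution(counts, source = "monte_carlo",
        nRealizations = nRealizations,
        seed = if (is.null(seed)) NA_real_ else seed,
        chrom = chrom, cnvType = cnvType)
}

#' Empirical upper-tail p-value
#'
#' The probability, under a null distribution of the hits statistic, of
#' observing at least as many hits as in the data: the summed histogram
#' mass at hit counts `>= observed`. For Monte Carlo nulls this is the
#' plain proportion `r / N`; `correction = "add-one"` gives the
#' guaranteed-positive variant `(r + 1) / (N + 1)`. For exact nulls it is
#' the analytic tail mass.
#'
#' @param null A [NullDistribution-class].
#' @param observed Observed hits statistic (non-negative integer).
#' @param correction `"none"` (default) or `"add-one"` (Monte Carlo nulls
#'   only).
#' @return A probability in `[0, 1]`.
#' @export
setGeneric("empiricalPvalue",
    function(null, observed, correction = c("none", "add-one"))
        standardGeneric("empiricalPvalue"))

#' @rdname empiricalPvalue
#' @export
setMethod("empiricalPvalue", "NullDistribution",
    function(null, observed, correction = c("none", "add-one")) {
        correction <- match.arg(correction)
        stopifnot(length(observed) == 1L, observed >= 0)
        sup <- as.numeric(names(null@counts))
        tail <- sum(null@counts[sup >= observed])
        if (identical(null@source, "exact"))
            return(min(1, tail))
        if (correction == "add-one")
            (tail + 1) / (null@nRealizations + 1)
        else
            tail / null@nRealizations
    })

#' Total-variation distance between two hit-count distributions
#'
#' Convenience for comparing a Monte Carlo histogram with the exact pmf:
#' both are normalised to probabilities and compared as
#' `0.5 * sum(|p - q|)` over the union of supports.
#'
#' @param a,b [NullDistribution-class] objects.
#' @return Total-variation distance in `[0, 1]`.
#' @export
tvDistance <- function(a, b) {
    stopifnot(is(a, "NullDistribution"), is(b, "NullDistribution"))
    pa <- a@counts / sum(a@counts)
    pb <- b@counts / sum(b@counts)
    sup <- union(names(pa), names(pb))
    pa <- ifelse(sup %in% names(pa), pa[sup], 0)
    pb <- ifelse(sup %in% names(pb), pb[sup], 0)
    0.5 * sum(abs(pa - pb))
}
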