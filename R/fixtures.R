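#' @include AllClasses.R
NULL

#' Generate a synthetic miRNA/CNV dataset
#'
#' Seeded generator for calibration and power studies. Per chromosome it
#' places `nGenes` miRNA-sized loci (lengths uniform in
#' `geneLengthRange`, defaults matching the 78-110 bp span of annotated
#' hairpin loci) uniformly and without mutual overlap, then, per CNV
#' type, draws `nCnvs` CNV lengths log-uniformly from `cnvLengthRange`
#' (kb-to-Mb scale) and places them. A fraction `enrichment` (q) of CNVs
#' per type is forced to cover a uniformly chosen gene: the CNV start is
#' drawn uniformly among the starts whose interval contains the whole
#' gene, clamped to the chromosome; the remaining CNVs are placed
#' uniformly among all positions keeping them inside the chromosome, i.e.
#' exactly the null model of [simulateNull()]. With `enrichment = 0` the
#' dataset is a draw from that null.
#'
#' @param chromLengths Named numeric vector of chromosome lengths
#'   (default one 10-Mb chromosome `"1"`).
#' @param nGenes Genes per chromosome.
#' @param geneLengthRange Integer range of gene lengths in bp.
#' @param nCnvs CNVs per chromosome and CNV type.
#' @param cnvTypes CNV types to generate (`"Gain"`, `"Loss"` or both).
#' @param cnvLengthRange Range of the log-uniform CNV length
#'   distribution, in bp (lengths are clamped to the chromosome).
#' @param enrichment Fraction q of CNVs per type forced to cover a gene;
#'   a scalar, or a vector named by chromosome for planted-enrichment
#'   designs (0 elsewhere).
#' @param seed Optional RNG seed; the dataset is a pure function of the
#'   arguments and the seed.
#' @return A [MirCnvDataset-class]; the generator call parameters are
#'   kept in its `metadata` slot.
#' @examples
#' ds <- simulateDataset(seed = 42)
#' summarizeCnvMirna(ds)
#' @export
simulateDataset <- function(chromLengths = c(`1` = 1e7), nGenes = 10,
        geneLengthRange = c(80, 110), nCnvs = 10,
        cnvTypes = c("Gain", "Loss"), cnvLengthRange = c(1e3, 1e6),
        enrichment = 0, seed = NULL) {
    stopifnot(length(chromLengths) >= 1, !is.null(names(chromLengths)),
        all(chromLengths >= 1), nGenes >= 0, nCnvs >= 0,
        all(cnvTypes %in% .CNV_TYPES),
        geneLengthRange[1L] >= 1,
        geneLengthRange[1L] <= geneLengthRange[2L],
        cnvLengthRange[1L] >= 1,
        cnvLengthRange[1L] <= cnvLengthRange[2L],
        all(enrichment >= 0 & enrichment <= 1))
    if (!is.null(seed))
        set.seed(seed)
    chroms <- names(chromLengths)
    q <- if (is.null(names(enrichment)))
        stats::setNames(rep(enrichment, length.out = length(chroms)), chroms)
    else
        stats::setNames(ifelse(chroms %in% names(enrichment),
            enrichment[chroms], 0), chroms)
    genome <- Seqinfo(seqnames = chroms,
        seqlengths = as.integer(chromLengths))
    geneList <- list()
    cnvList <- list()
    patientCounter <- 0L
    for (chrom in chroms) {
        G <- chromLengths[[chrom]]
        gl <- sample(seq(geneLengthRange[1L], geneLengthRange[2L]),
            nGenes, replace = TRUE)
        if (sum(gl) > G)
            stop(sprintf(
                "cannot place %d non-overlapping genes on chromosome %s",
                nGenes, chrom), call. = FALSE)
        gs <- ge <- numeric(0)
        for (len in gl) {
            placed <- FALSE
            for (try in seq_len(10000L)) {
                s <- sample.int(G - len + 1, 1L)
                e <- s + len - 1
                if (!any(s <= ge & e >= gs)) {
                    gs <- c(gs, s); ge <- c(ge, e)
                    placed <- TRUE
                    break
                }
            }
            if (!placed)
                stop(sprintf(
                    "cannot place %d non-overlapping genes on chromosome %s",
                    nGenes, chrom), call. = FALSE)
        }
        if (nGenes > 0L)
            geneList[[chrom]] <- GRanges(factor(chrom, levels = chroms),
                IRanges(gs, ge),
                strand = sample(c("+", "-"), nGenes, replace = TRUE),
                gene_id = sprintf("sim-mir-%s-%03d", chrom,
                    seq_len(nGenes)))
        for (type in cnvTypes) {
            if (nCnvs == 0L)
                next
            cl <- round(exp(runif(nCnvs, log(cnvLengthRange[1L]),
                log(min(cnvLengthRange[2L], G)))))
            cl <- pmin(pmax(cl, 1), G)
            nForced <- round(q[[chrom]] * nCnvs)
            starts <- numeric(nCnvs)
            for (j in seq_len(nCnvs)) {
                L <- cl[j]
                S <- G - L + 1
                if (j <= nForced && nGenes > 0L) {
                    g <- sample.int(nGenes, 1L)
                    lo <- max(1, ge[g] - L + 1)
                    hi <- min(S, gs[g])
                    if (lo > hi) {
                        ## CNV shorter than the gene: any overlapping
                        ## placement still guarantees a hit
                        lo <- max(1, gs[g] - L + 1)
                        hi <- min(S, ge[g])
                    }
                    starts[j] <- lo + sample.int(hi - lo + 1, 1L) - 1
                } else {
                    starts[j] <- sample.int(S, 1L)
                }
            }
            patients <- sprintf("P%03d", patientCounter + seq_len(nCnvs))
            patientCounter <- patientCounter + nCnvs
            cnvList[[paste(chrom, type)]] <- GRanges(
                factor(chrom, levels = chroms),
                IRanges(starts, width = cl),
                cnv_type = rep(type, nCnvs),
                patients = as(as.list(patients), "CharacterList"),
                n_patients = rep(1L, nCnvs),
                source = rep("case", nCnvs))
        }
    }
    emptyGr <- function() GRanges()
    genes <- if (length(geneList)) unname(do.call(c, unname(geneList)))
        else emptyGr()
    if (length(geneList) == 0L)
        mcols(genes)$gene_id <- character(0)
    cnvs <- if (length(cnvList)) unname(do.call(c, unname(cnvList)))
        else emptyGr()
    if (length(cnvList) == 0L) {
        mcols(cnvs)$cnv_type <- character(0)
        mcols(cnvs)$patients <- as(list(), "CharacterList")
        mcols(cnvs)$n_patients <- integer(0)
        mcols(cnvs)$source <- character(0)
    }
    MirCnvDataset(genome, genes, cnvs, metadata = list(
        generator = list(chromLengths = chromLengths, nGenes = nGenes,
            geneLengthRange = geneLengthRange, nCnvs = nCnvs,
            cnvTypes = cnvTypes, cnvLengthRange = cnvLengthRange,
            enrichment = enrichment, seed = seed)))
}

#' Write a dataset to plain-text files
#'
#' Persists a dataset as a `chrom.sizes` table, a miRBase-dialect GFF3 of
#' `miRNA_primary_transcript` features and a CNV TSV, plus a
#' `params.dcf` file recording the generator parameters when present.
#' The files round-trip through [readChromSizes()],
#' [readMirnaAnnotation()] and [readCnvTable()].
#'
#' @param x A [MirCnvDataset-class].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeDatasetFiles <- function(x, dir) {
    stopifnot(is(x, "MirCnvDataset"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
        genome = file.path(dir, "chrom.sizes"),
        mirna = file.path(dir, "mirna_genes.gff3"),
        cnv = file.path(dir, "cnv_calls.tsv"),
        params = file.path(dir, "params.dcf"))
    gnm <- seqinfo(x)
    writeLines(sprintf("%s\t%d", seqnames(gnm), seqlengths(gnm)),
        paths[["genome"]])
    genes <- mirnaGenes(x)
    strandChr <- as.character(strand(genes))
    strandChr[strandChr == "*"] <- "."
    gff <- c("##gff-version 3", sprintf(
        "%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
        as.character(seqnames(genes)), start(genes), end(genes),
        strandChr, mcols(genes)$gene_id, mcols(genes)$gene_id))
    writeLines(gff, paths[["mirna"]])
    writeCnvTable(cnvCalls(x), paths[["cnv"]])
    gen <- x@metadata$generator
    if (!is.null(gen)) {
        flat <- vapply(gen, function(v) {
            if (is.null(v)) "NULL"
            else paste(if (!is.null(names(v)))
                sprintf("%s=%s", names(v), format(v)) else format(v),
                collapse = ",")
        }, character(1L))
        write.dcf(as.data.frame(t(flat)), paths[["params"]])
    } else {
        paths <- paths[names(paths) != "params"]
    }
    invisible(paths)
}

#' Read a dataset written by writeDatasetFiles
#'
#' @param dir Directory containing `chrom.sizes`, `mirna_genes.gff3` and
#'   `cnv_calls.tsv`.
#' @param keepDuplicates Passed to [readCnvTable()].
#' @return A [MirCnvDataset-class].
#' @export
readDatasetFiles <- function(dir, keepDuplicates = FALSE) {
    genome <- readChromSizes(file.path(dir, "chrom.sizes"))
    genes <- readMirnaAnnotation(file.path(dir, "mirna_genes.gff3"),
        format = "gff3", genome = genome)
    cnvs <- readCnvTable(file.path(dir, "cnv_calls.tsv"), genome = genome,
        keepDuplicates = keepDuplicates)
    MirCnvDataset(genome, genes, cnvs)
}
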