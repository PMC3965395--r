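#' @include AllClasses.R
NULL

## Chromosome labels are matched with and without the UCSC "chr" prefix.
.normChrom <- function(x) sub("^chr", "", as.character(x))

#' Read a chromosome sizes table
#'
#' Reads a two-column, whitespace- or tab-delimited table of chromosome
#' name and length in bp (the common `chrom.sizes` layout). Lines starting
#' with `#` and blank lines are ignored; a leading `"chr"` prefix is
#' stripped from names so `"chr22"` and `"22"` refer to the same
#' chromosome.
#'
#' @param path Path to the table.
#'
#' @return A [Seqinfo] with one entry per input line, in file order.
#'
#' @examples
#' f <- tempfile()
#' writeLines(c("22\t51304566", "X\t155270560"), f)
#' readChromSizes(f)
#' @export
readChromSizes <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    lineno <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L)
        return(Seqinfo())
    fields <- strsplit(trimws(lines), "\\s+")
    nf <- lengths(fields)
    if (any(nf < 2L))
        stop(sprintf("chromosome sizes: line %d has fewer than 2 fields",
            lineno[which(nf < 2L)[1L]]), call. = FALSE)
    nm <- .normChrom(vapply(fields, `[`, character(1L), 1L))
    lenStr <- vapply(fields, `[`, character(1L), 2L)
    len <- suppressWarnings(as.numeric(lenStr))
    bad <- is.na(len) | len < 1 | len != round(len)
    if (any(bad))
        stop(sprintf(
            "chromosome sizes: line %d has non-integer or non-positive length '%s'",
            lineno[which(bad)[1L]], lenStr[which(bad)[1L]]), call. = FALSE)
    if (anyDuplicated(nm))
        stop(sprintf("chromosome sizes: duplicated chromosome name(s): %s",
            paste(unique(nm[duplicated(nm)]), collapse = ", ")),
            call. = FALSE)
    Seqinfo(seqnames = nm, seqlengths = as.integer(len))
}

#' Read a miRNA gene annotation
#'
#' Reads miRNA gene loci from a miRBase-style GFF3 (keeping only
#' `miRNA_primary_transcript` features, i.e. the genomic hairpin loci;
#' mature `miRNA` features are dropped), from BED (0-based half-open
#' coordinates are converted to the internal 1-based inclusive
#' convention), or from a TSV with 1-based inclusive columns
#' `chrom`, `start`, `end`, `gene_id` and optional `strand`.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (by file extension), `"gff3"`, `"bed"` or
#'   `"tsv"`.
#' @param genome Optional [Seqinfo]; when supplied, records on unknown
#'   chromosomes or beyond chromosome bounds raise an error listing the
#'   offending gene ids, and the returned ranges carry the genome's
#'   seqinfo.
#'
#' @return A [GRanges] with a `gene_id` metadata column. Gene ids must be
#'   unique; duplicates raise an error.
#'
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr5\t99\t199\tmirX", f)
#' readMirnaAnnotation(f)  # 1-based [100, 199]
#' @export
readMirnaAnnotation <- function(path, format = c("auto", "gff3", "bed", "tsv"),
        genome = NULL) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext,
            gff = , gff3 = "gff3",
            bed = "bed",
            tsv = , txt = "tsv",
            stop(sprintf("cannot guess annotation format from '%s'", path),
                call. = FALSE))
    }
    if (format == "gff3") {
        gr <- rtracklayer::import(path, format = "gff3")
        gr <- gr[mcols(gr)$type == "miRNA_primary_transcript"]
        id <- mcols(gr)$Name
        if (is.null(id)) id <- mcols(gr)$ID
        if (is.null(id))
            stop("GFF3 miRNA records carry neither Name nor ID attributes",
                call. = FALSE)
        id <- as.character(id)
    } else if (format == "bed") {
        gr <- rtracklayer::import(path, format = "bed")
        id <- mcols(gr)$name
        if (is.null(id)) id <- sprintf("mirna_%d", seq_along(gr))
    } else {
        tab <- read.delim(path, comment.char = "#",
            stringsAsFactors = FALSE)
        names(tab) <- tolower(names(tab))
        idcol <- intersect(c("gene_id", "name", "id"), names(tab))[1L]
        need <- c("chrom", "start", "end")
        if (!all(need %in% names(tab)) || is.na(idcol))
            stop("miRNA TSV requires columns chrom, start, end and gene_id",
                call. = FALSE)
        if (any(tab$start > tab$end))
            stop(sprintf("miRNA TSV: start > end at row(s) %s",
                paste(which(tab$start > tab$end), collapse = ", ")),
                call. = FALSE)
        strand <- if ("strand" %in% names(tab)) tab$strand else "*"
        strand[!strand %in% c("+", "-")] <- "*"
        gr <- GRanges(.normChrom(tab$chrom),
            IRanges(tab$start, tab$end), strand = strand)
        id <- as.character(tab[[idcol]])
    }
    gr <- GRanges(.normChrom(seqnames(gr)), ranges(gr), strand = strand(gr))
    mcols(gr) <- DataFrame(gene_id = id)
    if (anyDuplicated(id))
        stop(sprintf("duplicated miRNA gene_id(s): %s",
            paste(unique(id[duplicated(id)]), collapse = ", ")),
            call. = FALSE)
    if (!is.null(genome))
        gr <- .harmonizeSeqinfo(gr, genome, "miRNA gene")
    gr
}

#' Read a CNV table
#'
#' Reads a TSV of CNV calls with columns `chrom`, `start`, `end` (1-based
#' inclusive), `type` (`Gain`/`Loss`, case-insensitive) and optional
#' `patient`. Records identical on (chrom, start, end, type) are collapsed
#' into one call whose `patients` metadata column retains all contributing
#' patient ids; the number of collapsed duplicates is reported via
#' `message()`.
#'
#' @param path Path to the TSV (lines starting with `#` are ignored).
#' @param source `"case"` for patient (de novo) CNVs, `"population"` for
#'   DGV-style population CNVs; recorded in the `source` metadata column.
#' @param genome Optional [Seqinfo] used to validate chromosome labels and
#'   bounds.
#' @param keepDuplicates If `TRUE`, identical records are kept as separate
#'   calls (for sensitivity analyses).
#'
#' @return A [GRanges] with metadata columns `cnv_type`, `patients`
#'   ([CharacterList]), `n_patients` and `source`.
#'
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tstart\tend\ttype\tpatient",
#'     "1\t100\t5000\tGAIN\tP1", "1\t100\t5000\tgain\tP2"), f)
#' readCnvTable(f)  # one call, two patients
#' @export
readCnvTable <- function(path, source = c("case", "population"),
        genome = NULL, keepDuplicates = FALSE) {
    source <- match.arg(source)
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    names(tab)[names(tab) %in% c("chr", "chromosome")] <- "chrom"
    names(tab)[names(tab) %in% c("cnv_type")] <- "type"
    names(tab)[names(tab) %in% c("patient_id", "sample", "sample_id")] <-
        "patient"
    need <- c("chrom", "start", "end", "type")
    if (!all(need %in% names(tab)))
        stop(sprintf("CNV table requires columns %s",
            paste(need, collapse = ", ")), call. = FALSE)
    tl <- tolower(trimws(tab$type))
    bad <- !tl %in% c("gain", "loss")
    if (any(bad))
        stop(sprintf("CNV table: unrecognized type token(s): %s",
            paste(unique(tab$type[bad]), collapse = ", ")), call. = FALSE)
    type <- ifelse(tl == "gain", "Gain", "Loss")
    if (any(tab$start > tab$end))
        stop(sprintf("CNV table: start > end at row(s) %s",
            paste(which(tab$start > tab$end), collapse = ", ")),
            call. = FALSE)
    chrom <- .normChrom(tab$chrom)
    patient <- if ("patient" %in% names(tab))
        as.character(tab$patient) else rep(NA_character_, nrow(tab))
    ## writeCnvTable joins collapsed patient lists with commas
    patient <- strsplit(patient, ",", fixed = TRUE)
    key <- paste(chrom, tab$start, tab$end, type, sep = "\r")
    if (keepDuplicates) {
        idx <- seq_len(nrow(tab))
        patients <- as(lapply(patient, function(p) unique(p[!is.na(p)])),
            "CharacterList")
    } else {
        idx <- which(!duplicated(key))
        nDropped <- nrow(tab) - length(idx)
        if (nDropped > 0L)
            message(sprintf(
                "readCnvTable: collapsed %d duplicate CNV record(s)",
                nDropped))
        patients <- as(lapply(split(patient, factor(key, levels = key[idx])),
            function(p) {
                p <- unique(unlist(p))
                p[!is.na(p)]
            }), "CharacterList")
    }
    gr <- GRanges(chrom[idx], IRanges(tab$start[idx], tab$end[idx]))
    mcols(gr) <- DataFrame(
        cnv_type = type[idx],
        patients = unname(patients),
        n_patients = unname(lengths(patients)),
        source = rep(source, length(idx)))
    if (!is.null(genome))
        gr <- .harmonizeSeqinfo(gr, genome, "CNV")
    gr
}

#' Write a CNV table
#'
#' Writes CNV calls back to the TSV layout accepted by [readCnvTable()],
#' preceded by `#` header lines recording the package version and any
#' caller-supplied parameters. Collapsed patient lists are joined with
#' commas.
#'
#' @param cnvs A [GRanges] as returned by [readCnvTable()].
#' @param path Output path.
#' @param params Optional named list written into the header.
#'
#' @return `path`, invisibly.
#' @export
writeCnvTable <- function(cnvs, path, params = list()) {
    pat <- if ("patients" %in% colnames(mcols(cnvs)))
        vapply(mcols(cnvs)$patients, function(p) {
            p <- p[!is.na(p)]
            if (length(p) == 0L) NA_character_ else paste(p, collapse = ",")
        }, character(1L))
    else rep(NA_character_, length(cnvs))
    df <- data.frame(
        chrom = as.character(seqnames(cnvs)),
        start = start(cnvs), end = end(cnvs),
        type = mcols(cnvs)$cnv_type,
        patient = pat,
        stringsAsFactors = FALSE)
    .writeTsvWithHeader(df, path, params)
}

## Shared TSV writer: "#"-prefixed header lines with tool version and
## run parameters, then a plain header + rows; NA rendered as "N/A".
.writeTsvWithHeader <- function(df, path, params = list()) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# cnvMir %s", as.character(packageVersion("cnvMir"))),
        con)
    for (nm in names(params))
        writeLines(sprintf("# %s = %s", nm,
            paste(format(params[[nm]]), collapse = ",")), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
        na = "N/A")
    invisible(path)
}

## Read back a TSV written by .writeTsvWithHeader.
.readTsvWithHeader <- function(path) {
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
        na.strings = c("NA", "N/A"))
}
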