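#' @include AllClasses.R
NULL

## Load a genome given either a FASTA path or an already-read DNAStringSet.
## FASTA names are truncated at the first whitespace, as aligners do.
loadGenome <- function(fasta) {
    if (is(fasta, "DNAStringSet")) return(fasta)
    if (!is.character(fasta) || length(fasta) != 1L)
        stop("fasta must be a file path or a DNAStringSet")
    if (!file.exists(fasta))
        stop("FASTA file not found: ", fasta)
    genome <- readDNAStringSet(fasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
    genome
}

#' Read transcript models from a genePred file
#'
#' Parses a tab-delimited genePred table (UCSC knownGene dialect: name,
#' chrom, strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#' exonEnds, with 0-based half-open coordinates) and groups transcripts into
#' genes. Gene assignment uses, in order of preference: an explicit
#' \code{tx2gene} mapping; the \code{name2} column of the extended genePred
#' dialect (column 12); or strand-aware clustering of transcripts whose
#' exons overlap.
#'
#' @param path path to the genePred file.
#' @param fasta genome FASTA path or \code{DNAStringSet}; every chromosome
#'   named in the annotation must be present.
#' @param tx2gene optional data.frame with columns \code{transcriptId} and
#'   \code{geneId}.
#' @return a \code{\link{TranscriptModels}} object.
#' @seealso \code{\link{selectCassetteExons}}
#' @export
readGenePred <- function(path, fasta, tx2gene = NULL) {
    if (!file.exists(path)) stop("genePred file not found: ", path)
    genome <- loadGenome(fasta)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("genePred file is empty: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)

    parseIntList <- function(x, lineNo, what, expected) {
        v <- suppressWarnings(as.integer(strsplit(sub(",$", "", x),
                                                  ",")[[1L]]))
        if (length(v) != expected || anyNA(v))
            stop("genePred parse error at line ", lineNo, ": ", what,
                 " has ", length(v), " values but exonCount is ", expected)
        v
    }

    txId <- character(length(fields))
    chrom <- character(length(fields))
    std <- character(length(fields))
    name2 <- rep(NA_character_, length(fields))
    exonList <- vector("list", length(fields))
    for (i in seq_along(fields)) {
        f <- fields[[i]]
        if (length(f) < 10L)
            stop("genePred parse error at line ", i,
                 ": expected at least 10 tab-delimited fields, got ",
                 length(f))
        nExon <- suppressWarnings(as.integer(f[8L]))
        if (is.na(nExon) || nExon < 1L)
            stop("genePred parse error at line ", i, ": bad exonCount '",
                 f[8L], "'")
        starts <- parseIntList(f[9L], i, "exonStarts", nExon)
        ends <- parseIntList(f[10L], i, "exonEnds", nExon)
        if (any(ends <= starts))
            stop("genePred parse error at line ", i,
                 ": exonEnds must exceed exonStarts")
        if (!f[3L] %in% c("+", "-"))
            stop("genePred parse error at line ", i, ": bad strand '",
                 f[3L], "'")
        txId[i] <- f[1L]
        chrom[i] <- f[2L]
        std[i] <- f[3L]
        if (length(f) >= 12L && nzchar(f[12L])) name2[i] <- f[12L]
        ## 0-based half-open -> 1-based closed
        exonList[[i]] <- GRanges(f[2L], IRanges(starts + 1L, ends),
                                 strand = f[3L])
    }
    missingChrom <- setdiff(unique(chrom), names(genome))
    if (length(missingChrom))
        stop("chromosome(s) missing from FASTA: ",
             paste(missingChrom, collapse = ", "))
    if (anyDuplicated(txId))
        stop("duplicate transcript ids in genePred: ",
             paste(unique(txId[duplicated(txId)]), collapse = ", "))

    geneId <- assignGenes(txId, chrom, std, name2, exonList, tx2gene)
    exons <- GRangesList(setNames(exonList, txId))
    new("TranscriptModels", exons = exons,
        txGene = DataFrame(transcriptId = txId, geneId = geneId,
                           strand = std))
}

assignGenes <- function(txId, chrom, std, name2, exonList, tx2gene) {
    if (!is.null(tx2gene)) {
        if (!all(c("transcriptId", "geneId") %in% colnames(tx2gene)))
            stop("tx2gene must have columns transcriptId and geneId")
        idx <- match(txId, tx2gene$transcriptId)
        if (anyNA(idx))
            stop("tx2gene lacks entries for: ",
                 paste(txId[is.na(idx)], collapse = ", "))
        return(as.character(tx2gene$geneId[idx]))
    }
    if (!anyNA(name2)) return(name2)
    ## cluster transcripts whose exons overlap on the same strand
    spans <- GRanges(chrom,
                     IRanges(vapply(exonList, function(g) min(start(g)),
                                    integer(1L)),
                             vapply(exonList, function(g) max(end(g)),
                                    integer(1L))),
                     strand = std)
    red <- reduce(spans)
    hits <- findOverlaps(spans, red)
    cluster <- integer(length(spans))
    cluster[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
    paste0("gene", cluster)
}

## 1-based closed exon table for one transcript, sorted by genomic start.
exonTable <- function(gr) {
    o <- order(start(gr))
    cbind(start = start(gr)[o], end = end(gr)[o])
}
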