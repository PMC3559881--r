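#' @include genepred.R
NULL

#' Select cassette exons (ASEs) from transcript models
#'
#' An internal exon is selected as an ASE when (1) at least one isoform of
#' the gene includes it, (2) at least one isoform skips it, (3) the upstream
#' 5' splice site and the downstream 3' splice site are identical in all
#' isoforms, (4) the upstream 3' and downstream 5' splice sites (the ASE's
#' own boundaries) are identical in all including isoforms, and (5) both
#' flanking introns are at least \code{minIntronLen} nucleotides. Isoforms
#' that overlap the exon but can be classified neither as including (exact
#' internal exon) nor as excluding (an intron spanning the exon) disqualify
#' the candidate; isoforms that do not reach the exon are uninformative and
#' ignored. ASEs shared by several genes are deduplicated by
#' (chromosome, strand, interval).
#'
#' @param models a \code{\link{TranscriptModels}} object.
#' @param minIntronLen minimum flanking-intron length in nt. The default of
#'   400 guarantees that the two 200-nt windows taken from each intron by
#'   \code{\link{extractRegions}} never overlap.
#' @return a \code{\link{CassetteExons}} object.
#' @export
selectCassetteExons <- function(models, minIntronLen = 400) {
    stopifnot(is(models, "TranscriptModels"))
    byGene <- split(seq_len(nrow(models@txGene)), models@txGene$geneId)
    rows <- list()
    for (g in names(byGene)) {
        idx <- byGene[[g]]
        if (length(idx) < 2L) next
        exTabs <- lapply(models@exons[idx], exonTable)
        chroms <- vapply(idx, function(i)
            as.character(seqnames(models@exons[[i]])[1L]), character(1L))
        strands <- models@txGene$strand[idx]
        if (length(unique(chroms)) != 1L || length(unique(strands)) != 1L)
            next  # transcripts of one gene must share chrom and strand
        found <- selectAsesOneGene(exTabs, models@txGene$transcriptId[idx],
                                   minIntronLen)
        for (f in found) {
            f$geneId <- g
            f$chrom <- chroms[1L]
            f$strand <- strands[1L]
            rows[[length(rows) + 1L]] <- f
        }
    }
    if (!length(rows)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(aseId = character(0), geneId = character(0),
                               upIntron = IRanges(), dnIntron = IRanges(),
                               includingTx = CharacterList(),
                               excludingTx = CharacterList())
        return(new("CassetteExons", ranges = gr))
    }
    key <- vapply(rows, function(f)
        paste(f$chrom, f$strand, f$s, f$e, sep = ":"), character(1L))
    rows <- rows[!duplicated(key)]
    gr <- GRanges(vapply(rows, `[[`, character(1L), "chrom"),
                  IRanges(vapply(rows, `[[`, numeric(1L), "s"),
                          vapply(rows, `[[`, numeric(1L), "e")),
                  strand = vapply(rows, `[[`, character(1L), "strand"))
    ## flanking introns in transcript orientation
    left <- IRanges(vapply(rows, `[[`, numeric(1L), "leftIntronStart"),
                    vapply(rows, `[[`, numeric(1L), "leftIntronEnd"))
    right <- IRanges(vapply(rows, `[[`, numeric(1L), "rightIntronStart"),
                     vapply(rows, `[[`, numeric(1L), "rightIntronEnd"))
    plus <- as.character(strand(gr)) == "+"
    upIntron <- left
    upIntron[!plus] <- right[!plus]
    dnIntron <- right
    dnIntron[!plus] <- left[!plus]
    mcols(gr) <- DataFrame(
        aseId = sprintf("ase%05d", seq_along(gr)),
        geneId = vapply(rows, `[[`, character(1L), "geneId"),
        upIntron = upIntron, dnIntron = dnIntron,
        includingTx = CharacterList(lapply(rows, `[[`, "including")),
        excludingTx = CharacterList(lapply(rows, `[[`, "excluding")))
    new("CassetteExons", ranges = gr)
}

## Core of the five selection criteria, in genomic coordinates (the
## criteria are symmetric under strand flip). exTabs: list of 2-column
## matrices (start, end), 1-based closed, sorted.
selectAsesOneGene <- function(exTabs, txIds, minIntronLen) {
    ## candidate = any internal exon of any transcript
    cands <- unique(do.call(rbind, lapply(exTabs, function(tab) {
        if (nrow(tab) < 3L) return(NULL)
        tab[2:(nrow(tab) - 1L), , drop = FALSE]
    })))
    out <- list()
    if (is.null(cands)) return(out)
    for (k in seq_len(nrow(cands))) {
        s <- cands[k, 1L]; e <- cands[k, 2L]
        including <- character(0); excluding <- character(0)
        leftEnds <- integer(0); rightStarts <- integer(0)
        ok <- TRUE
        for (j in seq_along(exTabs)) {
            tab <- exTabs[[j]]
            hit <- which(tab[, 1L] == s & tab[, 2L] == e)
            overlaps <- any(tab[, 1L] <= e & tab[, 2L] >= s)
            if (length(hit) == 1L && hit > 1L && hit < nrow(tab)) {
                including <- c(including, txIds[j])
                leftEnds <- c(leftEnds, tab[hit - 1L, 2L])
                rightStarts <- c(rightStarts, tab[hit + 1L, 1L])
            } else if (!overlaps &&
                       any(tab[-nrow(tab), 2L] < s &
                           tab[-1L, 1L] > e)) {
                ## an intron of this isoform spans the exon: skipping
                i <- which(tab[-nrow(tab), 2L] < s & tab[-1L, 1L] > e)[1L]
                excluding <- c(excluding, txIds[j])
                leftEnds <- c(leftEnds, tab[i, 2L])
                rightStarts <- c(rightStarts, tab[i + 1L, 1L])
            } else if (overlaps) {
                ## exon variant with shifted boundaries, or terminal exon:
                ## splice sites not fixed -> criteria 3/4 violated
                ok <- FALSE
                break
            }  # else: transcript does not reach the exon; uninformative
        }
        if (!ok || !length(including) || !length(excluding)) next
        if (length(unique(leftEnds)) != 1L ||
            length(unique(rightStarts)) != 1L) next
        d <- leftEnds[1L]; a <- rightStarts[1L]
        leftIntron <- c(d + 1L, s - 1L)
        rightIntron <- c(e + 1L, a - 1L)
        if (diff(leftIntron) + 1L < minIntronLen ||
            diff(rightIntron) + 1L < minIntronLen) next
        out[[length(out) + 1L]] <- list(
            s = s, e = e, including = including, excluding = excluding,
            leftIntronStart = leftIntron[1L], leftIntronEnd = leftIntron[2L],
            rightIntronStart = rightIntron[1L],
            rightIntronEnd = rightIntron[2L])
    }
    out
}

#' Write an ASE table
#'
#' Tab-delimited summary of selected cassette exons with 1-based inclusive
#' coordinates and the comma-separated isoform sets.
#'
#' @param ases a \code{\link{CassetteExons}} object.
#' @param path output TSV path.
#' @return invisibly, the data.frame written.
#' @export
writeAseTable <- function(ases, path) {
    gr <- asGRanges(ases)
    mc <- mcols(gr)
    df <- data.frame(
        aseId = mc$aseId, geneId = mc$geneId,
        chrom = as.character(seqnames(gr)),
        strand = as.character(strand(gr)),
        exonStart = start(gr), exonEnd = end(gr),
        upIntronLen = width(mc$upIntron),
        dnIntronLen = width(mc$dnIntron),
        includingTx = vapply(mc$includingTx, paste, character(1L),
                             collapse = ","),
        excludingTx = vapply(mc$excludingTx, paste, character(1L),
                             collapse = ","),
        stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}
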