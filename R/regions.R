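#' @include ase-selection.R
NULL

## Splice-site consensus windows excluded from hexamer enumeration:
## at each 5' splice site, 3 exonic + 6 intronic nt (MAG/GURAGU);
## at each 3' splice site, 14 intronic + 1 exonic nt (polypyrimidine
## tract + YNCAG/G). Masking marks positions with N instead of shifting
## region boundaries.
DONOR_EXONIC <- 3L
DONOR_INTRONIC <- 6L
ACCEPTOR_INTRONIC <- 14L
ACCEPTOR_EXONIC <- 1L

## sense-oriented RNA sequence of genomic window [s, e] (1-based closed)
senseRna <- function(chromSeq, s, e, strand) {
    x <- subseq(chromSeq, s, e)
    if (strand == "-") x <- reverseComplement(x)
    chartr("Tt", "Uu", toupper(as.character(x)))
}

maskN <- function(x, from, to) {
    from <- max(1L, from); to <- min(nchar(x), to)
    if (from > to) return(x)
    substr(x, from, to) <- strrep("N", to - from + 1L)
    x
}

#' Extract the five masked sequence regions around each ASE
#'
#' For every cassette exon, returns sense-strand pre-mRNA sequences (T
#' replaced by U; minus-strand loci reverse-complemented) for the five
#' regions of the model: the 5' and 3' ends of the upstream intron (UU,
#' UD), the exon body (EXON), and the 5' and 3' ends of the downstream
#' intron (DU, DD). Intronic windows are \code{regionLen} nt; the exon is
#' used whole when shorter than \code{exonCap} nt and otherwise replaced by
#' the concatenation of its first and last \code{exonCap/2} nt (joined by
#' Ns so that no hexamer spans the junction). Splice-site consensus windows
#' are masked with N: 6 intronic nt after each 5' splice site, 14 intronic
#' nt before each 3' splice site, plus 3 exonic nt before the exon's 5'
#' splice site and 1 exonic nt after its 3' splice site.
#'
#' @param ases a \code{\link{CassetteExons}} object (selected with
#'   \code{minIntronLen >= 2 * regionLen} so that the two windows of an
#'   intron cannot overlap).
#' @param fasta genome FASTA path or \code{DNAStringSet}.
#' @param regionLen length of each intronic window (nt).
#' @param exonCap exon length above which only the two exon ends are used.
#' @return an \code{\link{AseRegionSet}}.
#' @export
extractRegions <- function(ases, fasta, regionLen = 200, exonCap = 200) {
    stopifnot(is(ases, "CassetteExons"))
    genome <- loadGenome(fasta)
    gr <- asGRanges(ases)
    mc <- mcols(gr)
    n <- length(gr)
    out <- list(UU = character(n), UD = character(n), EXON = character(n),
                DU = character(n), DD = character(n))
    half <- as.integer(exonCap %/% 2L)
    for (i in seq_len(n)) {
        chrom <- as.character(seqnames(gr)[i])
        if (!chrom %in% names(genome))
            stop("sequence retrieval failed for ", mc$aseId[i],
                 ": chromosome ", chrom, " not in FASTA")
        cs <- genome[[chrom]]
        std <- as.character(strand(gr)[i])
        s <- start(gr)[i]; e <- end(gr)[i]
        up <- c(start(mc$upIntron)[i], end(mc$upIntron)[i])
        dn <- c(start(mc$dnIntron)[i], end(mc$dnIntron)[i])
        if (max(e, up[2L], dn[2L]) > length(cs))
            stop("sequence retrieval failed for ", mc$aseId[i],
                 ": coordinates exceed chromosome ", chrom, " length")
        lUp <- min(regionLen, up[2L] - up[1L] + 1L)
        lDn <- min(regionLen, dn[2L] - dn[1L] + 1L)

        ## 5'/3' ends of an intron in transcript orientation
        fiveEnd <- function(iv, L) {
            if (std == "+") c(iv[1L], iv[1L] + L - 1L)
            else c(iv[2L] - L + 1L, iv[2L])
        }
        threeEnd <- function(iv, L) {
            if (std == "+") c(iv[2L] - L + 1L, iv[2L])
            else c(iv[1L], iv[1L] + L - 1L)
        }

        w <- fiveEnd(up, lUp)
        uu <- maskN(senseRna(cs, w[1L], w[2L], std), 1L, DONOR_INTRONIC)
        w <- threeEnd(up, lUp)
        ud <- senseRna(cs, w[1L], w[2L], std)
        ud <- maskN(ud, nchar(ud) - ACCEPTOR_INTRONIC + 1L, nchar(ud))
        w <- fiveEnd(dn, lDn)
        du <- maskN(senseRna(cs, w[1L], w[2L], std), 1L, DONOR_INTRONIC)
        w <- threeEnd(dn, lDn)
        dd <- senseRna(cs, w[1L], w[2L], std)
        dd <- maskN(dd, nchar(dd) - ACCEPTOR_INTRONIC + 1L, nchar(dd))

        exonWidth <- e - s + 1L
        if (exonWidth < exonCap) {
            ex <- senseRna(cs, s, e, std)
        } else {
            if (std == "+") {
                ex <- paste0(senseRna(cs, s, s + half - 1L, std),
                             strrep("N", 5L),
                             senseRna(cs, e - half + 1L, e, std))
            } else {
                ex <- paste0(senseRna(cs, e - half + 1L, e, std),
                             strrep("N", 5L),
                             senseRna(cs, s, s + half - 1L, std))
            }
        }
        ## exonic parts of the splice-site windows: 1 nt after the exon's
        ## own 3' splice site (its first base) and 3 nt before its 5'
        ## splice site (its last bases)
        ex <- maskN(ex, 1L, ACCEPTOR_EXONIC)
        ex <- maskN(ex, nchar(ex) - DONOR_EXONIC + 1L, nchar(ex))

        out$UU[i] <- uu; out$UD[i] <- ud; out$EXON[i] <- ex
        out$DU[i] <- du; out$DD[i] <- dd
    }
    ids <- mc$aseId
    regions <- lapply(out, function(x) {
        ss <- RNAStringSet(x)
        names(ss) <- ids
        ss
    })
    new("AseRegionSet", aseIds = as.character(ids), regions = regions)
}
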