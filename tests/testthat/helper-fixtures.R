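## Shared fixture builders: everything is generated in code at test time.

## AseRegionSet from a list of per-region character vectors
makeRegionSet <- function(...) {
    seqs <- list(...)
    stopifnot(identical(sort(names(seqs)), sort(spliceSRE:::REGION_LABELS)))
    n <- length(seqs[[1L]])
    ids <- sprintf("ase%03d", seq_len(n))
    regions <- lapply(seqs[spliceSRE:::REGION_LABELS], function(x) {
        ss <- Biostrings::RNAStringSet(x)
        names(ss) <- ids
        ss
    })
    new("AseRegionSet", aseIds = ids, regions = regions)
}

## pad a region so every sequence has the given length (background A/C)
padTo <- function(x, len) {
    vapply(x, function(s) {
        extra <- len - nchar(s)
        if (extra <= 0) return(s)
        paste0(s, paste(rep(c("A", "C"), length.out = extra),
                        collapse = ""))
    }, character(1L), USE.NAMES = FALSE)
}

## genePred line from exon starts/ends (0-based half-open)
gpLine <- function(name, chrom, strand, starts, ends, gene = NULL) {
    l <- paste(name, chrom, strand, min(starts), max(ends), min(starts),
               max(ends), length(starts),
               paste0(paste(starts, collapse = ","), ","),
               paste0(paste(ends, collapse = ","), ","), sep = "\t")
    if (!is.null(gene)) l <- paste(l, 0, gene, sep = "\t")
    l
}

## a toy two-isoform cassette-exon gene; returns list(genePred, genome)
## exon coords (0-based): e1 [50,170), ase [670,790), e3 [1290,1410)
toyCassetteGene <- function(strand = "+", seed = 1, chrom = "chr1",
                            gene = "g1") {
    set.seed(seed)
    seqLen <- 1460
    s <- paste(sample(c("A", "C", "G", "T"), seqLen, replace = TRUE),
               collapse = "")
    lines <- c(
        gpLine(paste0(gene, ".inc"), chrom, strand,
               c(50, 670, 1290), c(170, 790, 1410), gene),
        gpLine(paste0(gene, ".exc"), chrom, strand,
               c(50, 1290), c(170, 1410), gene))
    genome <- Biostrings::DNAStringSet(setNames(s, chrom))
    list(genePred = lines, genome = genome)
}

writeToyFiles <- function(toy, dir = withr::local_tempdir(.local_envir =
                                                          parent.frame())) {
    gp <- file.path(dir, "toy.genePred")
    fa <- file.path(dir, "toy.fa")
    writeLines(toy$genePred, gp)
    Biostrings::writeXStringSet(toy$genome, fa)
    list(genePred = gp, fasta = fa, dir = dir)
}

## reverse-complement an entire toy locus (genome + annotation), mirroring
## coordinates, so plus- and minus-strand extraction can be compared
mirrorToy <- function(toy) {
    chrom <- names(toy$genome)[1L]
    L <- Biostrings::width(toy$genome)[1L]
    rc <- Biostrings::reverseComplement(toy$genome)
    lines <- vapply(toy$genePred, function(l) {
        f <- strsplit(l, "\t")[[1L]]
        starts <- as.integer(strsplit(sub(",$", "", f[9L]), ",")[[1L]])
        ends <- as.integer(strsplit(sub(",$", "", f[10L]), ",")[[1L]])
        newStarts <- rev(L - ends)
        newEnds <- rev(L - starts)
        f[3L] <- if (f[3L] == "+") "-" else "+"
        f[4L] <- as.character(min(newStarts)); f[5L] <- as.character(max(newEnds))
        f[6L] <- f[4L]; f[7L] <- f[5L]
        f[9L] <- paste0(paste(newStarts, collapse = ","), ",")
        f[10L] <- paste0(paste(newEnds, collapse = ","), ",")
        paste(f, collapse = "\t")
    }, character(1L), USE.NAMES = FALSE)
    list(genePred = lines, genome = rc)
}

## wrap a plain 0/1 matrix as a SpliceFeatureMatrix of main-effect columns
wrapFeatureMatrix <- function(mat) asFeatureMatrix(mat)
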