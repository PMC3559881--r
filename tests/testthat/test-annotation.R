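test_that("genePred parsing preserves coordinates and reports bad lines", {
    toy <- toyCassetteGene()
    files <- writeToyFiles(toy)
    m <- readGenePred(files$genePred, files$fasta)
    expect_s4_class(m, "TranscriptModels")
    expect_length(m@exons, 2L)
    expect_identical(unique(m@txGene$geneId), "g1")
    # 0-based half-open input -> 1-based closed GRanges
    expect_equal(IRanges::start(m@exons[["g1.inc"]]), c(51, 671, 1291))
    expect_equal(IRanges::end(m@exons[["g1.inc"]]), c(170, 790, 1410))

    # exonCount mismatch names the offending line
    bad <- c(toy$genePred[1],
             "tx2\tchr1\t+\t50\t1410\t50\t1410\t3\t50,670,\t170,790,")
    bp <- file.path(files$dir, "bad.genePred")
    writeLines(bad, bp)
    expect_error(readGenePred(bp, files$fasta), "line 2")
    # missing chromosome in the FASTA is a named error
    miss <- sub("chr1", "chrZ", toy$genePred)
    mp <- file.path(files$dir, "miss.genePred")
    writeLines(miss, mp)
    expect_error(readGenePred(mp, files$fasta), "chrZ")
})

test_that("minus-strand transcripts keep genomic exon order", {
    toy <- toyCassetteGene(strand = "-")
    files <- writeToyFiles(toy)
    m <- readGenePred(files$genePred, files$fasta)
    ex <- m@exons[["g1.inc"]]
    expect_identical(as.character(BiocGenerics::strand(ex))[1], "-")
    expect_false(is.unsorted(IRanges::start(ex)))
})

test_that("transcripts without name2 are clustered into genes by overlap", {
    toy <- toyCassetteGene()
    # strip the gene column (plain 10-column genePred)
    lines <- vapply(strsplit(toy$genePred, "\t"), function(f)
        paste(f[1:10], collapse = "\t"), character(1))
    files <- writeToyFiles(list(genePred = lines, genome = toy$genome))
    m <- readGenePred(files$genePred, files$fasta)
    expect_length(unique(m@txGene$geneId), 1L)
})

test_that("the five selection criteria are individually falsifiable", {
    base <- toyCassetteGene()
    files <- writeToyFiles(base)
    sel <- function(lines, minIntron = 400) {
        p <- file.path(files$dir, "v.genePred")
        writeLines(lines, p)
        selectCassetteExons(readGenePred(p, files$fasta),
                            minIntronLen = minIntron)
    }
    # the canonical gene yields exactly one ASE (introns are 500 nt)
    ases <- sel(base$genePred)
    gr <- asGRanges(ases)
    expect_length(gr, 1L)
    expect_equal(IRanges::start(gr), 671)
    expect_equal(IRanges::end(gr), 790)
    mc <- S4Vectors::mcols(gr)
    expect_identical(unlist(mc$includingTx), "g1.inc")
    expect_identical(unlist(mc$excludingTx), "g1.exc")
    expect_equal(IRanges::width(mc$upIntron), 500)

    # criterion 1/2: no skipping isoform -> no ASE
    noSkip <- c(base$genePred[1],
                gpLine("g1.inc2", "chr1", "+", c(50, 670, 1290),
                       c(170, 790, 1410), "g1"))
    expect_length(asGRanges(sel(noSkip)), 0L)

    # criterion 3: skipping isoform with a different downstream 3' splice
    # site (the acceptor of the downstream exon moves)
    alt3 <- c(base$genePred[1],
              gpLine("g1.exc", "chr1", "+", c(50, 1310), c(170, 1410),
                     "g1"))
    expect_length(asGRanges(sel(alt3)), 0L)

    # criterion 3 upstream: different upstream 5' splice site
    alt5 <- c(base$genePred[1],
              gpLine("g1.exc", "chr1", "+", c(50, 1290), c(150, 1410),
                     "g1"))
    expect_length(asGRanges(sel(alt5)), 0L)

    # criterion 4: a second including isoform with a shifted ASE boundary
    alt4 <- c(base$genePred,
              gpLine("g1.inc2", "chr1", "+", c(50, 670, 1290),
                     c(170, 770, 1410), "g1"))
    expect_length(asGRanges(sel(alt4)), 0L)

    # criterion 5: intron below the minimum length
    expect_length(asGRanges(sel(base$genePred, minIntron = 501)), 0L)
    expect_length(asGRanges(sel(base$genePred, minIntron = 500)), 1L)
})

test_that("shared exons are deduplicated by coordinates", {
    t1 <- toyCassetteGene(gene = "g1")
    t2 <- toyCassetteGene(gene = "g2")  # same coordinates, other gene
    files <- writeToyFiles(list(
        genePred = c(t1$genePred,
                     sub("g1", "g2", t2$genePred)),
        genome = t1$genome))
    ases <- selectCassetteExons(readGenePred(files$genePred, files$fasta))
    expect_length(asGRanges(ases), 1L)
})

test_that("regions are sense-strand RNA with masked splice windows", {
    toy <- toyCassetteGene()
    files <- writeToyFiles(toy)
    ases <- selectCassetteExons(readGenePred(files$genePred, files$fasta))
    regs <- extractRegions(ases, files$fasta)
    s <- lapply(regionSeqs(regs), function(x) as.character(x[[1]]))
    chrom <- as.character(toy$genome[[1]])
    # UU: first 200 nt of the upstream intron (genomic [171, 370]),
    # first 6 masked
    expect_identical(substr(s$UU, 1, 6), "NNNNNN")
    expect_identical(substr(s$UU, 7, 200),
                     chartr("T", "U", substr(chrom, 177, 370)))
    # UD: last 200 nt of the upstream intron, last 14 masked
    expect_identical(substr(s$UD, 187, 200), strrep("N", 14))
    expect_identical(substr(s$UD, 1, 186),
                     chartr("T", "U", substr(chrom, 471, 656)))
    # EXON is 120 nt (< cap): whole exon, first 1 and last 3 masked
    expect_equal(nchar(s$EXON), 120)
    expect_identical(substr(s$EXON, 1, 1), "N")
    expect_identical(substr(s$EXON, 118, 120), "NNN")
    expect_identical(substr(s$EXON, 2, 117),
                     chartr("T", "U", substr(chrom, 672, 787)))
    # DU starts with the donor mask, DD ends with the acceptor mask
    expect_identical(substr(s$DU, 1, 6), "NNNNNN")
    expect_identical(substr(s$DD, 187, 200), strrep("N", 14))
    # unmasked intronic content: 194 on 5' sides, 186 on 3' sides
    countACGU <- function(x) nchar(gsub("N", "", x))
    expect_lte(countACGU(s$UU), 194)
    expect_lte(countACGU(s$DD), 186)
})

test_that("long exons are capped to their two 100-nt ends", {
    toy <- toyCassetteGene()
    # widen the ASE to 300 nt: [670, 970), shift downstream exon
    lines <- c(
        gpLine("g1.inc", "chr1", "+", c(50, 670, 1290), c(170, 970, 1410),
               "g1"),
        gpLine("g1.exc", "chr1", "+", c(50, 1290), c(170, 1410), "g1"))
    files <- writeToyFiles(list(genePred = lines, genome = toy$genome))
    ases <- selectCassetteExons(readGenePred(files$genePred, files$fasta),
                                minIntronLen = 300)
    regs <- extractRegions(ases, files$fasta, regionLen = 150)
    ex <- as.character(regionSeqs(regs)$EXON[[1]])
    chrom <- as.character(toy$genome[[1]])
    expect_equal(nchar(ex), 205)  # 100 + 5 N + 100
    expect_identical(substr(ex, 101, 105), "NNNNN")
    expect_identical(substr(ex, 2, 100),
                     chartr("T", "U", substr(chrom, 672, 770)))
    expect_identical(substr(ex, 106, 202),
                     chartr("T", "U", substr(chrom, 871, 967)))
    # no hexamer can span the two blocks
    expect_false(any(grepl("N",
                           hexamersInSequence(ex), fixed = TRUE)))
})

test_that("plus- and minus-strand versions of a locus give identical
           region sequences", {
    toy <- toyCassetteGene(seed = 8)
    mir <- mirrorToy(toy)
    fP <- writeToyFiles(toy)
    fM <- writeToyFiles(mir)
    rP <- extractRegions(selectCassetteExons(
        readGenePred(fP$genePred, fP$fasta)), fP$fasta)
    rM <- extractRegions(selectCassetteExons(
        readGenePred(fM$genePred, fM$fasta)), fM$fasta)
    for (r in spliceSRE:::REGION_LABELS)
        expect_identical(as.character(regionSeqs(rM)[[r]][[1]]),
                         as.character(regionSeqs(rP)[[r]][[1]]))
})

test_that("a hand reverse-complemented toy window matches extraction", {
    # build a minus-strand gene and check UU against a hand revcomp
    toy <- toyCassetteGene(strand = "-", seed = 5)
    files <- writeToyFiles(toy)
    ases <- selectCassetteExons(readGenePred(files$genePred, files$fasta))
    regs <- extractRegions(ases, files$fasta, regionLen = 12)
    chrom <- as.character(toy$genome[[1]])
    # minus strand: upstream intron is genomic [791, 1290]; its 5' end is
    # the genomic right end [1279, 1290], reverse complemented
    win <- substr(chrom, 1279, 1290)
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(win)))
    expected <- chartr("T", "U", rc)
    substr(expected, 1, 6) <- "NNNNNN"   # donor-side mask
    expect_identical(as.character(regionSeqs(regs)$UU[[1]]), expected)
})
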