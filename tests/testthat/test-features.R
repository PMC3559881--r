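test_that("hexamer enumeration skips masked windows and records presence", {
    expect_identical(hexamersInSequence("ACGUAC"), "ACGUAC")
    # a 7-mer yields its two constituent hexamers
    expect_setequal(hexamersInSequence("UGCAUGU"), c("UGCAUG", "GCAUGU"))
    # every window touches the N
    expect_identical(hexamersInSequence("ACGNACGUA"), character(0))
    expect_identical(hexamersInSequence("ACGUA"), character(0))
    # repeats count once (presence, not occurrence)
    expect_identical(hexamersInSequence("AAAAAAAA"), "AAAAAA")
    expect_error(hexamersInSequence("ACGTAC"), "outside")
})

test_that("hexamer universe covers all 4096 RNA hexamers", {
    u <- hexamerUniverse()
    expect_length(u, 4096)
    expect_false(anyDuplicated(u) > 0)
    expect_true(all(nchar(u) == 6))
    expect_true(all(grepl("^[ACGU]+$", u)))
})

test_that("main-effect matrix records region-specific presence", {
    rs <- makeRegionSet(
        UU = padTo(c("UGCAUGA", "AAAAAAA", "AAAAAAA"), 12),
        UD = padTo(c("CCCCCCC", "CCCCCCC", "CCCCCCC"), 12),
        EXON = padTo(c("GGGGGGG", "GGGGGGG", "GGGGGGG"), 12),
        DU = padTo(c("UGCAUGA", "AAAAAAA", "UGCAUGA"), 12),
        DD = padTo(c("UUUUUUU", "UUUUUUU", "UUUUUUU"), 12))
    fm <- buildFeatureMatrix(rs, minPresence = 0)
    m <- designMatrix(fm)
    expect_equal(as.vector(m[, "UGCAUG:DU"]), c(1, 0, 1))
    # same hexamer in two regions gives two distinct columns
    expect_true(all(c("UGCAUG:UU", "UGCAUG:DU") %in% colnames(m)))
    expect_equal(as.vector(m[, "UGCAUG:UU"]), c(1, 0, 0))
    info <- featureInfo(fm)
    expect_true(all(info$type == "SRE"))
    expect_equal(unname(info["UGCAUG:DU", "presence"]), 2 / 3)
})

test_that("low-presence columns are dropped and counted", {
    rs <- makeRegionSet(
        UU = padTo(c("UGCAUGA", rep("AAAAAAA", 5)), 12),
        UD = padTo(rep("CCCCCCC", 6), 12),
        EXON = padTo(rep("GGGGGGG", 6), 12),
        DU = padTo(rep("AAAAAAA", 6), 12),
        DD = padTo(rep("UUUUUUU", 6), 12))
    fm <- buildFeatureMatrix(rs, minPresence = 0.4)
    expect_false("UGCAUG:UU" %in% colnames(designMatrix(fm)))  # 1/6 < 0.4
    expect_true("AAAAAA:DU" %in% colnames(designMatrix(fm)))   # 6/6
    expect_gt(S4Vectors::metadata(featureInfo(fm))$droppedLowPresence, 0)
})

test_that("pair columns are elementwise products with pair metadata", {
    mat <- cbind(a = c(1, 0, 1, 1), b = c(1, 1, 0, 1), c = c(0, 1, 1, 0))
    colnames(mat) <- c("AAAAAA:UU", "CCCCCC:DU", "GGGGGG:UU")
    fm <- wrapFeatureMatrix(mat)
    fm2 <- buildPairColumns(fm, rbind(c("AAAAAA:UU", "CCCCCC:DU")),
                            minPresence = 0)
    m <- designMatrix(fm2)
    expect_equal(as.vector(m[, "AAAAAA:UU|CCCCCC:DU"]), c(1, 0, 0, 1))
    info <- featureInfo(fm2)
    expect_identical(info["AAAAAA:UU|CCCCCC:DU", "type"], "pair")
    expect_identical(info["AAAAAA:UU|CCCCCC:DU", "region2"], "DU")
    # same-region pairs are allowed
    fm3 <- buildPairColumns(fm, rbind(c("AAAAAA:UU", "GGGGGG:UU")),
                            minPresence = 0)
    expect_true("AAAAAA:UU|GGGGGG:UU" %in% colnames(designMatrix(fm3)))
    # product never present -> dropped under any positive threshold
    mat2 <- cbind(mat, d = c(0, 0, 0, 0))
    colnames(mat2)[4] <- "UUUUUU:DD"
    fm4 <- buildPairColumns(wrapFeatureMatrix(mat2),
                            rbind(c("AAAAAA:UU", "UUUUUU:DD")),
                            minPresence = 0.01)
    expect_false(any(featureInfo(fm4)$type == "pair"))
    # referencing an absent parent is an error
    expect_error(buildPairColumns(fm, rbind(c("AAAAAA:UU", "NNNNNN:DD"))),
                 "absent")
})

test_that("region pairs fall into the 15 unordered classes", {
    labs <- spliceSRE:::REGION_LABELS
    combos <- t(combn(labs, 2))
    classes <- unique(c(regionPairClass(combos[, 1], combos[, 2]),
                        regionPairClass(labs, labs)))
    expect_length(classes, 15)
    expect_identical(regionPairClass("DU", "UD"), "UD-DU")
    expect_identical(regionPairClass("UD", "DU"), "UD-DU")
    expect_identical(regionPairClass("UU", "UU"), "UU-UU")
    expect_error(regionPairClass("UU", "XX"), "region labels")
})

test_that("matrix construction is deterministic and order-independent", {
    set.seed(9)
    seqs <- lapply(1:5, function(i)
        vapply(1:8, function(j)
            paste(sample(c("A", "C", "G", "U"), 30, TRUE), collapse = ""),
            character(1)))
    names(seqs) <- spliceSRE:::REGION_LABELS
    rs <- do.call(makeRegionSet, seqs)
    fm1 <- buildFeatureMatrix(rs, minPresence = 0)
    fm2 <- buildFeatureMatrix(rs, minPresence = 0)
    expect_identical(as.matrix(designMatrix(fm1)),
                     as.matrix(designMatrix(fm2)))
    # permuting the ASEs permutes rows but leaves columns identical
    perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
    seqsP <- lapply(seqs, function(x) x[perm])
    rsP <- do.call(makeRegionSet, seqsP)
    fmP <- buildFeatureMatrix(rsP, minPresence = 0)
    expect_identical(colnames(designMatrix(fmP)),
                     colnames(designMatrix(fm1)))
    expect_equal(as.matrix(designMatrix(fmP)),
                 as.matrix(designMatrix(fm1))[perm, ],
                 ignore_attr = TRUE)
})

test_that("hexamersInSequence agrees with the matrix construction route", {
    set.seed(31)
    seqs <- vapply(1:6, function(i)
        paste(sample(c("A", "C", "G", "U", "N"), 40, TRUE,
                     prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
              collapse = ""), character(1))
    rs <- makeRegionSet(UU = seqs, UD = seqs, EXON = seqs, DU = seqs,
                        DD = seqs)
    fm <- buildFeatureMatrix(rs, minPresence = 0)
    m <- designMatrix(fm)
    for (i in seq_along(seqs)) {
        fromSet <- sort(paste0(hexamersInSequence(seqs[i]), ":UU"))
        fromMat <- sort(grep(":UU$", colnames(m)[m[i, ] == 1],
                             value = TRUE))
        expect_identical(fromMat, fromSet)
    }
})
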