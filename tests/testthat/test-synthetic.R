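test_that("scenario validation rejects malformed inputs", {
    expect_error(sreScenario(planted = data.frame(
        hexamer = "ACGT", region = "UU", cf = 2, presenceProb = 0.2)),
        "hexamers")
    expect_error(sreScenario(planted = data.frame(
        hexamer = "ACGUAC", region = "XX", cf = 2, presenceProb = 0.2)),
        "regions")
    pl <- data.frame(hexamer = c("ACGUAC", "UGCAUG"), region = "UU",
                     cf = 2, presenceProb = 0.2)
    expect_error(sreScenario(planted = pl,
                             pairs = data.frame(idx1 = 1, idx2 = 3,
                                                cPair = 2, pBoth = 0.1,
                                                pSolo = 0.1)),
                 "reference planted rows")
    expect_s3_class(sreScenario(planted = pl), "SreScenario")
})

test_that("planted presence equals the sampled indicator exactly", {
    pl <- data.frame(hexamer = c("UGCAUG", "CUCUCU"),
                     region = c("DU", "UD"), cf = c(3, 1/3),
                     presenceProb = c(0.3, 1.0))
    sc <- sreScenario(nAses = 600, nTissues = 3, regionLen = 60,
                      planted = pl, seed = 4)
    plant <- plantSequences(sc)
    seqs <- regionSeqs(plant$regions)
    # realized presence from the sequences matches the indicator
    duHit <- grepl("UGCAUG", as.character(seqs$DU), fixed = TRUE)
    expect_identical(as.integer(duHit), unname(plant$presence[, 1]))
    udHit <- grepl("CUCUCU", as.character(seqs$UD), fixed = TRUE)
    expect_identical(as.integer(udHit), unname(plant$presence[, 2]))
    # presence probability 1 -> all ones; 0.3 concentrates around 0.3
    expect_true(all(plant$presence[, 2] == 1))
    expect_gt(mean(plant$presence[, 1]), 0.25)
    expect_lt(mean(plant$presence[, 1]), 0.35)
    # determinism
    plant2 <- plantSequences(sc)
    expect_identical(lapply(regionSeqs(plant2$regions), as.character),
                     lapply(seqs, as.character))
    # motif longer than the region
    expect_error(plantSequences(sreScenario(regionLen = 6, planted = pl,
                                            nAses = 5)),
                 NA)
    tiny <- sreScenario(regionLen = 7, planted = pl, nAses = 5)
    tiny$regionLen <- 5L
    expect_error(plantSequences(tiny), "longer")
})

test_that("paired motifs co-occur as configured", {
    pl <- data.frame(hexamer = c("UGCAUG", "GGGGCA"),
                     region = c("DU", "DD"), cf = 3, presenceProb = 0.2)
    prs <- data.frame(idx1 = 1, idx2 = 2, cPair = 0.01,
                      pBoth = 0.2, pSolo = 0.05)
    sc <- sreScenario(nAses = 2000, nTissues = 3, regionLen = 40,
                      planted = pl, pairs = prs, seed = 6)
    plant <- plantSequences(sc)
    both <- mean(plant$presence[, 1] * plant$presence[, 2])
    expect_gt(both, 0.17); expect_lt(both, 0.23)
    solo <- mean(plant$presence[, 1] == 1 & plant$presence[, 2] == 0)
    expect_gt(solo, 0.02); expect_lt(solo, 0.08)
})

test_that("linear simulation honors effects and noise", {
    set.seed(2)
    mat <- matrix(rbinom(400 * 4, 1, 0.4), 400, 4)
    colnames(mat) <- c("AAAAAA:UU", "CCCCCC:DU", "GGGGGG:DD",
                       "UUUUUU:UD")
    fm <- wrapFeatureMatrix(mat)
    eff <- c("AAAAAA:UU" = 1.5, "CCCCCC:DU" = -1)
    y0 <- simulateLinear(fm, eff, sigma = 0, seed = 3)
    expect_equal(as.vector(y0),
                 as.vector(mat[, 1] * 1.5 - mat[, 2]))
    # residual variance concentrates near sigma^2
    big <- wrapFeatureMatrix(matrix(rbinom(1e4, 1, 0.3), 1e4, 1))
    yN <- simulateLinear(big, c("HEX0001:UU" = 1), sigma = 1, seed = 9)
    expect_equal(var(yN - attr(yN, "signal")), 1, tolerance = 0.05)
    # a pure pair effect is nonzero only where both parents are present
    fmP <- buildPairColumns(fm, rbind(c("AAAAAA:UU", "CCCCCC:DU")),
                            minPresence = 0)
    yP <- simulateLinear(fmP, c("AAAAAA:UU|CCCCCC:DU" = 2), sigma = 0)
    expect_true(all(yP[mat[, 1] * mat[, 2] == 0] == 0))
    expect_true(all(yP[mat[, 1] * mat[, 2] == 1] == 2))
    expect_error(simulateLinear(fm, c(ZZZ = 1), 1), "absent")
})

test_that("biophysical simulation matches the occupancy decomposition
           at zero noise", {
    pl <- data.frame(hexamer = c("UGCAUG", "CUCUCU"),
                     region = c("DU", "UD"), cf = c(4, 0.25),
                     presenceProb = 0.4)
    prs <- data.frame(idx1 = 1, idx2 = 2, cPair = 0.05,
                      pBoth = 0.25, pSolo = 0.2)
    sc <- sreScenario(nAses = 150, nTissues = 4, regionLen = 30,
                      planted = pl, pairs = prs, noiseSigma = 0,
                      seed = 12)
    sim <- simulateBiophysical(sc)
    resp <- computeResponse(sim$ir, clipEpsilon = 1e-6)
    y <- responses(resp)
    # dual route: rebuild the expected centered response from the
    # occupancy terms and the planted presence
    g <- rbind(sfContribution(sim$xMat[1, ], pl$cf[1]),
               sfContribution(sim$xMat[2, ], pl$cf[2]))
    pairT <- vapply(seq_len(ncol(sim$xMat)), function(t)
        decomposeLogRatio(1, 1, x = sim$xMat[, t], cf = pl$cf,
                          cPair = 0.05)$pairTerm, numeric(1))
    expected <- sim$presence %*% g +
        outer(sim$presence[, 1] * sim$presence[, 2], pairT)
    expected <- expected - rowMeans(expected)
    expect_equal(unname(y), unname(expected), tolerance = 1e-10)
})

test_that("expression tables embed the inclusion ratios", {
    sc <- sreScenario(nAses = 40, nTissues = 3, regionLen = 30, seed = 3)
    sim <- simulateBiophysical(sc)
    expect_true(all(sim$expr$expression >= 0))
    sub <- sim$expr[sim$expr$tissue == sim$tissues[1], ]
    inc <- sub$expression[endsWith(sub$isoformId, ".inc")]
    exc <- sub$expression[endsWith(sub$isoformId, ".exc")]
    expect_equal(inc / (inc + exc), unname(sim$ir[, 1]),
                 tolerance = 1e-12)
    # totals respect the 3 RPKM floor of the draw
    expect_true(all(inc + exc > 2.4))
})

test_that("noise calibration hits the target explained variance", {
    sc <- benchmarkScenario(nAses = 800, seed = 19)
    sim <- simulateBiophysical(sc)
    y <- responses(computeResponse(sim$ir))[, sim$truth$targetTissue]
    sig <- (sim$logit - rowMeans(sim$logit))[, 1]
    r2 <- 100 * (1 - var(y - sig) / var(y))
    expect_gt(r2, 50); expect_lt(r2, 70)
})

test_that("recovery evaluation counts exact matches, pairs unordered", {
    truth <- list(mainKeys = c("AAAAAA:UU", "CCCCCC:DU"),
                  pairKeys = "AAAAAA:UU|CCCCCC:DU")
    r <- evaluateRecovery(c("AAAAAA:UU", "CCCCCC:DU",
                            "CCCCCC:DU|AAAAAA:UU"), truth)
    expect_equal(r$pooled$precision, 1)
    expect_equal(r$pooled$recall, 1)
    expect_equal(r$pairs$recall, 1)   # reversed order still matches
    r2 <- evaluateRecovery(c("AAAAAA:UU", "GGGGGG:DD"), truth)
    expect_equal(r2$mains$precision, 0.5)
    expect_equal(r2$mains$recall, 0.5)
    expect_equal(r2$pairs$recall, 0)
    r3 <- evaluateRecovery(character(0), truth)
    expect_true(is.na(r3$pooled$precision))
    expect_equal(r3$pooled$recall, 0)
})

test_that("toy locus generator writes a parseable annotated genome", {
    dir <- withr::local_tempdir()
    toy <- simulateToyLocus(nGenes = 2, seed = 3, dir = dir)
    m <- readGenePred(toy$genePredPath, toy$fastaPath)
    expect_length(m@exons, 4L)
    ases <- selectCassetteExons(m)
    expect_length(asGRanges(ases), 2L)
})
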