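#' @include biophysics.R
#' @include features.R
NULL

randomRna <- function(nSeq, len, gc = 0.5, asMatrix = FALSE) {
    prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    m <- matrix(sample(RNA_BASES, nSeq * len, replace = TRUE, prob = prob),
                nrow = nSeq)
    if (asMatrix) m else apply(m, 1L, paste, collapse = "")
}

#' Define a synthetic splicing scenario
#'
#' Bundles the generative conditions for the forward simulators: the number
#' of ASEs and tissues, background sequence composition, the planted SREs
#' (hexamer, region, SF-spliceosome cooperativity, presence probability)
#' and planted cooperative pairs. Cooperative pairs co-occur more often
#' than independence (jointly present with probability \code{pBoth}, each
#' member alone with probability \code{pSolo}), as pairs detectable by
#' co-occurrence screening must.
#'
#' @param nAses number of ASEs.
#' @param nTissues number of tissues.
#' @param regionLen length (nt) of each of the five generated regions.
#' @param gc background GC content (i.i.d. nucleotides).
#' @param planted data.frame with columns \code{hexamer}, \code{region},
#'   \code{cf} (SF-spliceosome cooperativity; 1 = inert) and
#'   \code{presenceProb}.
#' @param pairs data.frame with columns \code{idx1}, \code{idx2} (row
#'   numbers into \code{planted}), \code{cPair}, \code{pBoth},
#'   \code{pSolo}; a planted SRE may belong to at most one pair.
#' @param xLow,xHigh,nHighTissues per-SF occupancy weights: \code{xHigh}
#'   in \code{nHighTissues} randomly chosen tissues, \code{xLow} elsewhere.
#' @param targetR2 fraction of response variance the true model should
#'   explain in the target tissue (noise is calibrated to this).
#' @param noiseSigma fixed logit-scale noise SD; overrides \code{targetR2}
#'   when given.
#' @param seed integer seed (all generators are bit-reproducible under it).
#' @return a validated scenario list (class \code{"SreScenario"}).
#' @export
sreScenario <- function(nAses = 1200, nTissues = 9, regionLen = 200,
                        gc = 0.5, planted = NULL, pairs = NULL,
                        xLow = 0.1, xHigh = 5, nHighTissues = 3,
                        targetR2 = 0.6, noiseSigma = NULL, seed = 1) {
    if (is.null(planted))
        planted <- data.frame(hexamer = character(0), region = character(0),
                              cf = numeric(0), presenceProb = numeric(0))
    stopifnot(all(c("hexamer", "region", "cf", "presenceProb") %in%
                  colnames(planted)))
    if (nrow(planted)) {
        if (any(nchar(planted$hexamer) != 6L) ||
            any(grepl("[^ACGU]", planted$hexamer)))
            stop("planted motifs must be hexamers over A/C/G/U")
        if (!all(planted$region %in% REGION_LABELS))
            stop("planted regions must be among ",
                 paste(REGION_LABELS, collapse = ", "))
        if (any(planted$presenceProb < 0 | planted$presenceProb > 1))
            stop("presence probabilities must lie in [0, 1]")
        if (any(planted$cf <= 0)) stop("cooperativities must be positive")
        if (anyDuplicated(paste(planted$hexamer, planted$region)))
            stop("planted (hexamer, region) combinations must be distinct")
    }
    if (!is.null(pairs) && nrow(pairs)) {
        stopifnot(all(c("idx1", "idx2", "cPair", "pBoth", "pSolo") %in%
                      colnames(pairs)))
        idx <- c(pairs$idx1, pairs$idx2)
        if (any(idx < 1 | idx > nrow(planted)))
            stop("pair indices must reference planted rows")
        if (anyDuplicated(idx))
            stop("a planted SRE may belong to at most one pair")
        if (any(pairs$pBoth + pairs$pSolo > 1))
            stop("pBoth + pSolo must not exceed 1")
    } else {
        pairs <- data.frame(idx1 = integer(0), idx2 = integer(0),
                            cPair = numeric(0), pBoth = numeric(0),
                            pSolo = numeric(0))
    }
    if (regionLen < 6L) stop("regions must allow at least one hexamer")
    if (!is.null(noiseSigma) && noiseSigma < 0)
        stop("noiseSigma must be non-negative")
    structure(list(nAses = as.integer(nAses),
                   nTissues = as.integer(nTissues),
                   regionLen = as.integer(regionLen), gc = gc,
                   planted = planted, pairs = pairs, xLow = xLow,
                   xHigh = xHigh, nHighTissues = as.integer(nHighTissues),
                   targetR2 = targetR2, noiseSigma = noiseSigma,
                   seed = as.integer(seed)),
              class = "SreScenario")
}

## presence indicators for planted motifs, honoring pair co-occurrence
samplePresence <- function(scenario) {
    nP <- nrow(scenario$planted)
    pres <- matrix(0L, scenario$nAses, nP)
    paired <- c(scenario$pairs$idx1, scenario$pairs$idx2)
    for (k in seq_len(nrow(scenario$pairs))) {
        i <- scenario$pairs$idx1[k]; j <- scenario$pairs$idx2[k]
        u <- runif(scenario$nAses)
        both <- u < scenario$pairs$pBoth[k]
        soloI <- !both & (runif(scenario$nAses) < scenario$pairs$pSolo[k])
        soloJ <- !both & (runif(scenario$nAses) < scenario$pairs$pSolo[k])
        pres[, i] <- as.integer(both | soloI)
        pres[, j] <- as.integer(both | soloJ)
    }
    for (f in setdiff(seq_len(nP), paired))
        pres[, f] <- rbinom(scenario$nAses, 1L,
                            scenario$planted$presenceProb[f])
    pres
}

#' The standard benchmark scenario
#'
#' The synthetic study conditions used throughout the package's validation:
#' 1200 ASEs across 9 tissues; ten planted SREs spread over the five
#' regions (presence probability 0.2 for unpaired SREs); three planted
#' antagonistic pairs among those SREs (SF-SF cooperativity 0.002: the
#' bound partner blocks the other SF's coupling to the spliceosome, which
#' gives a strong tissue contrast, whereas mutually cooperative binding
#' saturates; jointly present in 10\% of ASEs, each member alone in
#' 15\%, keeping the product column distinguishable from its parents).
#' The six paired SREs carry SF-spliceosome cooperativity 5 (or
#' 1/5 for silencers) and the four unpaired ones 3 (or 1/3): cooperative
#' terms are partially collinear with their parents, so detectable pairs
#' in practice involve the strongest, most differentially expressed SFs.
#' SF occupancy weights are 5 in four of the nine tissues and 0.1
#' elsewhere (so the centered per-SF effects are comparable in magnitude
#' whether or not the target tissue is among the elevated ones);
#' logit-scale Gaussian noise is calibrated so the true model explains
#' about 60\% of the response variance in the target tissue.
#'
#' @param nAses,nTissues problem size (defaults are the study conditions).
#' @param seed integer seed.
#' @return an \code{\link{sreScenario}}.
#' @export
benchmarkScenario <- function(nAses = 1200, nTissues = 9, seed = 1) {
    planted <- data.frame(
        hexamer = c("UGCAUG", "CUCUCU", "ACUAAC", "UGCUGC", "GGGGCA",
                    "UGGGGA", "CCCCAG", "AUUUAU", "UUUUAU", "CCAGGG"),
        region = c("DU", "UD", "UD", "UU", "DU",
                   "DD", "UU", "UU", "DD", "EXON"),
        cf = c(5, 1/5, 1/3, 5, 1/3, 5, 5, 3, 1/5, 3),
        presenceProb = 0.2)
    pairs <- data.frame(
        idx1 = c(1L, 2L, 4L), idx2 = c(6L, 9L, 7L),
        cPair = 0.002,
        pBoth = 0.10, pSolo = 0.15)
    sreScenario(nAses = nAses, nTissues = nTissues, planted = planted,
                pairs = pairs, nHighTissues = 4, targetR2 = 0.6,
                seed = seed)
}

#' Plant motifs into random background sequences
#'
#' Generates i.i.d. background nucleotides at the configured GC content for
#' the five regions of every ASE, then inserts each planted motif at a
#' uniformly random position of its region in the sampled carrier subset.
#' Insertions never overlap each other; the base on each side of an
#' insertion is masked (N), so a planted motif contributes exactly its own
#' hexamer and no shifted-variant windows; and accidental background
#' occurrences of a planted motif in non-carrier sequences are scrubbed
#' (one base mutated). Together these make the realized feature column
#' equal the sampled indicator exactly, so that recovery against the truth
#' table is unambiguous.
#'
#' @param scenario an \code{\link{sreScenario}}.
#' @param seed integer seed; defaults to the scenario's.
#' @return list with \code{regions} (an \code{\link{AseRegionSet}}),
#'   \code{presence} (integer matrix, ASEs x planted motifs, named by
#'   \code{"HEXAMER:REGION"} keys) and \code{scenario}.
#' @export
plantSequences <- function(scenario, seed = scenario$seed) {
    stopifnot(inherits(scenario, "SreScenario"))
    if (nrow(scenario$planted) &&
        any(nchar(scenario$planted$hexamer) > scenario$regionLen))
        stop("a planted motif is longer than the region")
    set.seed(seed)
    n <- scenario$nAses
    L <- scenario$regionLen
    seqs <- lapply(setNames(REGION_LABELS, REGION_LABELS), function(r)
        randomRna(n, L, scenario$gc, asMatrix = TRUE))
    pres <- samplePresence(scenario)
    keys <- character(nrow(scenario$planted))
    ## insert carriers without overlap between insertions
    occupied <- lapply(REGION_LABELS, function(r)
        vector("list", n))
    names(occupied) <- REGION_LABELS
    for (f in seq_len(nrow(scenario$planted))) {
        hex <- strsplit(scenario$planted$hexamer[f], "")[[1L]]
        r <- scenario$planted$region[f]
        keys[f] <- paste0(scenario$planted$hexamer[f], ":", r)
        for (i in which(pres[, f] == 1L)) {
            placed <- FALSE
            for (try in seq_len(100L)) {
                s <- sample.int(L - 5L, 1L)
                iv <- c(max(1L, s - 1L), min(L, s + 6L))  # motif + N flanks
                clash <- any(vapply(occupied[[r]][[i]], function(o)
                    iv[1L] <= o[2L] && iv[2L] >= o[1L], logical(1L)))
                if (!clash) {
                    seqs[[r]][i, s:(s + 5L)] <- hex
                    if (s > 1L) seqs[[r]][i, s - 1L] <- "N"
                    if (s + 6L <= L) seqs[[r]][i, s + 6L] <- "N"
                    occupied[[r]][[i]] <-
                        c(occupied[[r]][[i]], list(iv))
                    placed <- TRUE
                    break
                }
            }
            if (!placed)
                stop("could not place motif ", keys[f], " in ASE ", i,
                     " without overlap")
        }
    }
    ## scrub accidental background occurrences in non-carriers
    strings <- lapply(seqs, function(m) apply(m, 1L, paste, collapse = ""))
    for (f in seq_len(nrow(scenario$planted))) {
        hex <- scenario$planted$hexamer[f]
        r <- scenario$planted$region[f]
        nonCarrier <- which(pres[, f] == 0L)
        for (round in seq_len(10L)) {
            hit <- nonCarrier[grepl(hex, strings[[r]][nonCarrier],
                                    fixed = TRUE)]
            if (!length(hit)) break
            for (i in hit) {
                pos <- regexpr(hex, strings[[r]][i], fixed = TRUE)
                mut <- pos + sample.int(6L, 1L) - 1L
                old <- substr(strings[[r]][i], mut, mut)
                substr(strings[[r]][i], mut, mut) <-
                    sample(setdiff(RNA_BASES, old), 1L)
            }
        }
    }
    ids <- sprintf("ase%05d", seq_len(n))
    regions <- lapply(strings, function(x) {
        ss <- RNAStringSet(x); names(ss) <- ids; ss
    })
    colnames(pres) <- keys
    rownames(pres) <- ids
    list(regions = new("AseRegionSet", aseIds = ids,
                       regions = regions[REGION_LABELS]),
         presence = pres, scenario = scenario)
}

#' Simulate responses from the linear model
#'
#' \eqn{y = \sum_k \gamma_k s_k + \sum_{kl} \gamma_{kl} s_k s_l + \epsilon}
#' with i.i.d. Gaussian measurement error.
#'
#' @param fm a \code{\link{SpliceFeatureMatrix}} (or 0/1 matrix) whose
#'   columns include the effect names.
#' @param effects named numeric vector of true coefficients (main and/or
#'   pair columns).
#' @param sigma noise standard deviation.
#' @param seed integer seed.
#' @return numeric response vector with attribute \code{"signal"} (the
#'   noiseless linear predictor).
#' @export
simulateLinear <- function(fm, effects, sigma, seed = 1) {
    mat <- if (is(fm, "SpliceFeatureMatrix")) designMatrix(fm) else fm
    if (!all(names(effects) %in% colnames(mat)))
        stop("effects name columns absent from the matrix: ",
             paste(setdiff(names(effects), colnames(mat)), collapse = ", "))
    signal <- as.vector(mat[, names(effects), drop = FALSE] %*% effects)
    set.seed(seed)
    y <- signal + rnorm(nrow(mat), 0, sigma)
    attr(y, "signal") <- signal
    y
}

#' Simulate isoform expression through the thermodynamic model
#'
#' Draws per-ASE basal weights and exon constants, per-SF tissue occupancy
#' profiles (elevated in a few tissues, low elsewhere), composes the logit
#' isoform ratio additively from the per-SF Boltzmann terms
#' (\code{\link{sfContribution}}) and the pair terms of
#' \code{\link{decomposeLogRatio}}, adds Gaussian logit-scale measurement
#' noise, and emits a two-isoform expression table with total gene
#' expression drawn log-uniformly in [3, 300] RPKM. Noise is calibrated so
#' the true (centered) model explains \code{targetR2} of the response
#' variance in the target tissue, unless \code{noiseSigma} is set.
#'
#' @param scenario an \code{\link{sreScenario}}.
#' @param targetTissue index of the tissue used for calibration and truth.
#' @param seed integer seed.
#' @return list with \code{expr} (expression data.frame), \code{regions},
#'   \code{presence}, \code{truth} (see \code{\link{evaluateRecovery}}),
#'   \code{ir} and \code{logit} matrices, \code{tissues}, and the noise
#'   \code{sigma} used.
#' @export
simulateBiophysical <- function(scenario, targetTissue = 1L,
                                seed = scenario$seed) {
    stopifnot(inherits(scenario, "SreScenario"))
    plant <- plantSequences(scenario, seed = seed)
    ## continue the RNG stream after sequence generation
    n <- scenario$nAses
    Tn <- scenario$nTissues
    nP <- nrow(scenario$planted)
    tissues <- sprintf("tissue%02d", seq_len(Tn))
    q0 <- exp(runif(n, log(0.5), log(2)))
    exonConst <- exp(runif(n, log(0.5), log(2)))
    xMat <- matrix(scenario$xLow, nP, Tn)
    for (f in seq_len(nP)) {
        hi <- sample.int(Tn, scenario$nHighTissues)
        xMat[f, hi] <- scenario$xHigh
    }
    ## cooperating SFs are co-expressed: pair members share one profile
    for (k in seq_len(nrow(scenario$pairs)))
        xMat[scenario$pairs$idx2[k], ] <- xMat[scenario$pairs$idx1[k], ]
    logit <- matrix(log(exonConst * q0), n, Tn)
    gTerms <- matrix(0, nP, Tn)       # per-SF contribution by tissue
    for (f in seq_len(nP))
        gTerms[f, ] <- sfContribution(xMat[f, ], scenario$planted$cf[f])
    if (nP)
        logit <- logit + plant$presence %*% gTerms
    pairTerms <- matrix(0, nrow(scenario$pairs), Tn)
    if (nrow(scenario$pairs)) {
        for (k in seq_len(nrow(scenario$pairs))) {
            i <- scenario$pairs$idx1[k]; j <- scenario$pairs$idx2[k]
            for (t in seq_len(Tn)) {
                pairTerms[k, t] <- decomposeLogRatio(
                    1, 1, x = c(xMat[i, t], xMat[j, t]),
                    cf = scenario$planted$cf[c(i, j)],
                    cPair = scenario$pairs$cPair[k])$pairTerm
            }
            both <- plant$presence[, i] * plant$presence[, j]
            logit <- logit + outer(both, pairTerms[k, ])
        }
    }
    ## center across tissues: the signal the inference sees
    centered <- logit - rowMeans(logit)
    sigma <- scenario$noiseSigma
    if (is.null(sigma)) {
        vs <- var(centered[, targetTissue])
        sigma <- if (vs > 0)
            sqrt(vs * (1 - scenario$targetR2) / scenario$targetR2 /
                 (1 - 1 / Tn))
        else 0
    }
    noise <- matrix(rnorm(n * Tn, 0, sigma), n, Tn)
    noisy <- logit + noise
    ir <- plogis(noisy)
    dimnames(ir) <- list(plant$regions@aseIds, tissues)
    total <- exp(runif(n, log(3), log(300)))
    total <- matrix(rep(total, Tn), n, Tn) *
        exp(matrix(rnorm(n * Tn, 0, 0.1), n, Tn))
    expr <- data.frame(
        isoformId = rep(c(paste0(rownames(ir), ".inc"),
                          paste0(rownames(ir), ".exc")), Tn),
        geneId = rep(rep(paste0("gene.", rownames(ir)), 2L), Tn),
        tissue = rep(tissues, each = 2L * n),
        expression = as.vector(rbind(
            matrix(total * ir, n, Tn),
            matrix(total * (1 - ir), n, Tn))),
        stringsAsFactors = FALSE)
    active <- which(scenario$planted$cf != 1)
    gammaTarget <- (gTerms - rowMeans(gTerms))[, targetTissue]
    pairGammaTarget <- if (nrow(pairTerms))
        (pairTerms - rowMeans(pairTerms))[, targetTissue] else numeric(0)
    truth <- list(
        mainKeys = colnames(plant$presence)[active],
        mainGamma = setNames(gammaTarget[active],
                             colnames(plant$presence)[active]),
        pairKeys = if (nrow(scenario$pairs))
            paste0(colnames(plant$presence)[scenario$pairs$idx1], "|",
                   colnames(plant$presence)[scenario$pairs$idx2])
        else character(0),
        pairGamma = pairGammaTarget,
        targetTissue = tissues[targetTissue])
    list(expr = expr, regions = plant$regions, presence = plant$presence,
         truth = truth, ir = ir, logit = logit, tissues = tissues,
         sigma = sigma, xMat = xMat)
}

canonicalPairKey <- function(key) {
    vapply(strsplit(key, "|", fixed = TRUE), function(p)
        paste(sort(p), collapse = "|"), character(1L))
}

#' Precision and recall of a recovered model against planted truth
#'
#' Exact-match comparison of FDR-passing features against the planted
#' (hexamer, region) keys; pairs are matched unordered. Precision is
#' \code{NA} when nothing was recovered.
#'
#' @param fit an \code{\link{SreFit}} (or a character vector of recovered
#'   keys).
#' @param truth the \code{truth} element of
#'   \code{\link{simulateBiophysical}}, or a list with \code{mainKeys} and
#'   \code{pairKeys}.
#' @return list of precision/recall for mains, pairs and pooled.
#' @export
evaluateRecovery <- function(fit, truth) {
    if (is(fit, "SreFit")) {
        res <- modelResults(fit)
        res <- res[res$passesFdr, , drop = FALSE]
        recMain <- res$key[res$type == "SRE"]
        recPair <- res$key[res$type == "pair"]
    } else {
        recMain <- fit[!grepl("|", fit, fixed = TRUE)]
        recPair <- fit[grepl("|", fit, fixed = TRUE)]
    }
    recPair <- canonicalPairKey(recPair)
    trueMain <- truth$mainKeys
    truePair <- canonicalPairKey(truth$pairKeys)
    pr <- function(rec, tru) {
        tp <- length(intersect(rec, tru))
        list(precision = if (length(rec)) tp / length(rec) else NA_real_,
             recall = if (length(tru)) tp / length(tru) else NA_real_)
    }
    mains <- pr(recMain, trueMain)
    pairs <- pr(recPair, truePair)
    pooled <- pr(c(recMain, recPair), c(trueMain, truePair))
    list(mains = mains, pairs = pairs, pooled = pooled)
}

#' Write region sequences as FASTA
#'
#' One record per (ASE, region), named \code{aseId|REGION}.
#'
#' @param regionSet an \code{\link{AseRegionSet}}.
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
writeRegionFasta <- function(regionSet, path) {
    all <- do.call(c, lapply(REGION_LABELS, function(r) {
        ss <- regionSeqs(regionSet)[[r]]
        names(ss) <- paste0(aseIds(regionSet), "|", r)
        ss
    }))
    writeXStringSet(all, path)
    invisible(path)
}

#' Generate a toy annotated locus set
#'
#' Builds a small genome and genePred annotation of cassette-exon genes
#' (three exons, one including and one skipping isoform each) for testing
#' the annotation-driven path of the pipeline.
#'
#' @param nGenes number of genes.
#' @param exonLen,intronLen,flankLen exon, intron and outer-flank lengths
#'   (nt).
#' @param seed integer seed.
#' @param dir output directory; when given, writes \code{toy.genePred},
#'   \code{toy.fa} and returns their paths in the result.
#' @return list with \code{genome} (\code{DNAStringSet}),
#'   \code{genePredLines}, and file paths when \code{dir} was given.
#' @export
simulateToyLocus <- function(nGenes = 3, exonLen = 120, intronLen = 500,
                             flankLen = 50, seed = 1, dir = NULL) {
    set.seed(seed)
    lines <- character(0)
    chromSeqs <- character(nGenes)
    for (g in seq_len(nGenes)) {
        total <- 2L * flankLen + 3L * exonLen + 2L * intronLen
        seq <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
                     collapse = "")
        chromSeqs[g] <- seq
        e1s <- flankLen                       # 0-based starts
        e1e <- e1s + exonLen
        e2s <- e1e + intronLen
        e2e <- e2s + exonLen
        e3s <- e2e + intronLen
        e3e <- e3s + exonLen
        strand <- if (g %% 2L == 0L) "-" else "+"
        chrom <- paste0("chr", g)
        gene <- paste0("g", g)
        lines <- c(lines,
            paste(paste0(gene, ".inc"), chrom, strand, e1s, e3e, e1s, e3e,
                  3, paste0(e1s, ",", e2s, ",", e3s, ","),
                  paste0(e1e, ",", e2e, ",", e3e, ","), 0, gene,
                  sep = "\t"),
            paste(paste0(gene, ".exc"), chrom, strand, e1s, e3e, e1s, e3e,
                  2, paste0(e1s, ",", e3s, ","),
                  paste0(e1e, ",", e3e, ","), 0, gene, sep = "\t"))
    }
    genome <- DNAStringSet(setNames(chromSeqs,
                                    paste0("chr", seq_len(nGenes))))
    out <- list(genome = genome, genePredLines = lines)
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        gp <- file.path(dir, "toy.genePred")
        fa <- file.path(dir, "toy.fa")
        writeLines(lines, gp)
        writeXStringSet(genome, fa)
        out$genePredPath <- gp
        out$fastaPath <- fa
    }
    out
}
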