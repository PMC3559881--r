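#' @include screening.R
#' @include selection.R
#' @include regions.R
#' @include response.R
NULL

#' Four-stage SRE inference for one tissue
#'
#' Runs the inference framework on one tissue's centered logit responses:
#' (1) marginal screening of all main-effect columns and interaction
#' screening of pairs among the retained ones (with hypergeometric
#' co-occurrence and presence filters); (2) Lasso with CV-selected penalty
#' followed by an adaptive Lasso path weighted by the inverse Lasso
#' coefficients; (3) refitted cross-validation (RCV) estimation of the
#' residual variance; (4) choice of the final penalty as the sparsest model
#' whose OLS-refit variance still exceeds the RCV estimate, an OLS refit
#' with two-sided t-tests, and Benjamini-Hochberg selection at the target
#' FDR. Effect signs are classified from splicing-factor expression when
#' available.
#'
#' @param y numeric response vector parallel to the rows of \code{fm};
#'   \code{NA} entries (ASEs dropped in this tissue) are removed.
#' @param fm \code{\link{SpliceFeatureMatrix}} of main-effect columns.
#' @param tissue tissue label carried into the result.
#' @param screenAlpha,coocAlpha p-value thresholds of the screening stage.
#' @param minPresence presence threshold for features and products.
#' @param cvFolds cross-validation folds for the Lasso penalty.
#' @param rcvRepeats number of RCV split repeats.
#' @param rcvCvFolds CV folds used inside each RCV half.
#' @param rcvScreenAlpha per-half re-screening level inside RCV; strict
#'   by default because the candidate columns have already passed the
#'   global screen (see \code{\link{rcvVariance}}).
#' @param fdr target false discovery rate of the final selection.
#' @param seed integer seed; drives CV fold assignment and RCV splits.
#' @param sfExpression optional data.frame (sf, tissue, expression) of
#'   splicing-factor expression for effect-sign calls.
#' @param sfMotifs optional data.frame (sf, hexamer) mapping motifs to the
#'   SF assumed to bind them.
#' @return an \code{\link{SreFit}}.
#' @export
fitSreModel <- function(y, fm, tissue = "tissue", screenAlpha = 0.05,
                        coocAlpha = 0.05, minPresence = 0.01,
                        cvFolds = 100, rcvRepeats = 100, rcvCvFolds = 10,
                        rcvScreenAlpha = 0.001, fdr = 0.05, seed = 1,
                        sfExpression = NULL, sfMotifs = NULL) {
    stopifnot(is(fm, "SpliceFeatureMatrix"))
    keep <- !is.na(y)
    y <- y[keep]
    mat <- designMatrix(fm)[keep, , drop = FALSE]
    fmT <- new("SpliceFeatureMatrix", mat = mat, info = featureInfo(fm))
    n <- length(y)
    notes <- character(0)

    emptyFit <- function(note) {
        new("SreFit", tissue = tissue,
            results = DataFrame(type = character(0),
                                hexamer1 = character(0),
                                region1 = character(0),
                                hexamer2 = character(0),
                                region2 = character(0),
                                key = character(0),
                                coefficient = numeric(0), se = numeric(0),
                                pValue = numeric(0), qValue = numeric(0),
                                passesFdr = logical(0),
                                occurrences = integer(0),
                                effect = character(0)),
            sigma2Rcv = NA_real_,
            residVariance = if (n > 1) var(y) else NA_real_,
            lambda = NA_real_, r2 = 0, n = as.integer(n),
            dropped = character(0), notes = c(notes, note))
    }
    if (n < 20L) return(emptyFit("fewer than 20 usable ASEs"))

    ms <- marginalScreen(y, fmT, alpha = screenAlpha)
    s1 <- ms$key[ms$kept]
    if (!length(s1)) return(emptyFit("no columns passed marginal screening"))
    isc <- interactionScreen(y, fmT, s1, alpha = screenAlpha,
                             coocAlpha = coocAlpha,
                             minPresence = minPresence)
    fmS <- subsetFeatures(fmT, s1)
    keptPairs <- which(isc$kept)
    if (length(keptPairs))
        fmS <- buildPairColumns(fmS,
                                cbind(isc$parent1[keptPairs],
                                      isc$parent2[keptPairs]),
                                minPresence = minPresence)
    X <- designMatrix(fmS)
    if (ncol(X) < 2L) {
        # a single screened column: the penalized stages need >= 2
        # columns; refit it directly
        ols <- olsRefitFdr(X, y, colnames(X), fdr = fdr)
        occ <- as.integer(Matrix::colSums(X))
        info <- featureInfo(fmS)
        results <- DataFrame(type = info$type, hexamer1 = info$hexamer1,
                             region1 = info$region1,
                             hexamer2 = info$hexamer2,
                             region2 = info$region2,
                             key = ols$table$key,
                             coefficient = ols$table$coefficient,
                             se = ols$table$se,
                             pValue = ols$table$pValue,
                             qValue = ols$table$qValue,
                             passesFdr = ols$table$passesFdr,
                             occurrences = occ,
                             effect = rep("unknown", nrow(ols$table)),
                             row.names = ols$table$key)
        return(new("SreFit", tissue = tissue, results = results,
                   sigma2Rcv = NA_real_,
                   residVariance = ols$residVariance, lambda = NA_real_,
                   r2 = ols$r2, n = as.integer(n),
                   dropped = ols$dropped,
                   notes = c(notes, "single screened column; penalized ",
                             "stages skipped")))
    }

    cvL <- cvSelectLambda(X, y, folds = cvFolds, seed = seed)
    b <- cvL$betaMin
    if (all(b == 0)) return(emptyFit("CV-selected Lasso model is empty"))
    ad <- withCallingHandlers(
        adaptiveLassoPath(X, y, b),
        warning = function(w) {
            notes <<- c(notes, conditionMessage(w))
            invokeRestart("muffleWarning")
        })
    rcv <- withCallingHandlers(
        rcvVariance(X, y, repeats = rcvRepeats, seed = seed + 1L,
                    cvFolds = rcvCvFolds, screenAlpha = rcvScreenAlpha),
        warning = function(w) {
            notes <<- c(notes, conditionMessage(w))
            invokeRestart("muffleWarning")
        })
    finalSel <- withCallingHandlers(
        selectFinalLambda(ad, X, y, rcv),
        warning = function(w) {
            notes <<- c(notes, conditionMessage(w))
            invokeRestart("muffleWarning")
        })
    if (length(finalSel$selected) >= n - 1L) {
        return(emptyFit(paste0("selected set (", length(finalSel$selected),
                               ") as large as the sample; model ",
                               "unidentifiable")))
    }
    if (!length(finalSel$selected))
        return(new("SreFit", tissue = tissue,
                   results = emptyFit("")@results,
                   sigma2Rcv = rcv@sigma2,
                   residVariance = finalSel$residVariance,
                   lambda = finalSel$lambda, r2 = 0, n = as.integer(n),
                   dropped = character(0),
                   notes = c(notes, "final selection is empty")))

    ols <- olsRefitFdr(X, y, finalSel$selected, fdr = fdr)
    info <- featureInfo(fmS)[ols$table$key, ]
    occ <- as.integer(round(Matrix::colSums(
        X[, ols$table$key, drop = FALSE])))
    effect <- rep("unknown", nrow(ols$table))
    if (!is.null(sfExpression) && !is.null(sfMotifs)) {
        effect <- effectCalls(ols$table, info, tissue, sfExpression,
                              sfMotifs)
    }
    results <- DataFrame(type = info$type,
                         hexamer1 = info$hexamer1,
                         region1 = info$region1,
                         hexamer2 = info$hexamer2,
                         region2 = info$region2,
                         key = ols$table$key,
                         coefficient = ols$table$coefficient,
                         se = ols$table$se,
                         pValue = ols$table$pValue,
                         qValue = ols$table$qValue,
                         passesFdr = ols$table$passesFdr,
                         occurrences = occ,
                         effect = effect,
                         row.names = ols$table$key)
    new("SreFit", tissue = tissue, results = results,
        sigma2Rcv = rcv@sigma2, residVariance = ols$residVariance,
        lambda = finalSel$lambda, r2 = ols$r2, n = as.integer(n),
        dropped = ols$dropped, notes = notes)
}

## effect-sign calls for single SREs (pairs stay "unknown": the sign of a
## pair coefficient does not identify enhancement or silencing)
effectCalls <- function(table, info, tissue, sfExpression, sfMotifs) {
    stopifnot(all(c("sf", "tissue", "expression") %in%
                  colnames(sfExpression)),
              all(c("sf", "hexamer") %in% colnames(sfMotifs)))
    vapply(seq_len(nrow(table)), function(i) {
        if (info$type[i] != "SRE") return("unknown")
        sf <- sfMotifs$sf[match(info$hexamer1[i], sfMotifs$hexamer)]
        if (is.na(sf)) return("unknown")
        rows <- sfExpression$sf == sf
        conc <- setNames(sfExpression$expression[rows],
                         sfExpression$tissue[rows])
        if (!tissue %in% names(conc) || any(conc <= 0)) return("unknown")
        call <- classifyEffect(sign(table$coefficient[i]), conc, tissue)
        if (call == "indeterminate") "unknown" else call
    }, character(1L))
}

#' Configuration for the file-based pipeline
#'
#' @param annotation genePred path.
#' @param fasta genome FASTA path.
#' @param expression isoform expression TSV path (isoformId, geneId,
#'   tissue, expression).
#' @param outDir output directory.
#' @param sfExpression,sfMotifs optional TSV paths for effect-sign calls.
#' @param tissues tissue subset (default: all in the expression table).
#' @param minIntronLen,regionLen,exonCap annotation/region parameters (nt).
#' @param rpkmThreshold gene-expression filter (RPKM, strict).
#' @param clipEpsilon inclusion-ratio clipping constant.
#' @param screenAlpha,coocAlpha,minPresence screening thresholds.
#' @param cvFolds,rcvRepeats,rcvCvFolds,rcvScreenAlpha,fdr inference
#'   parameters.
#' @param seed master seed; every random draw in the run derives from it.
#' @return config list for \code{\link{runSrePipeline}}.
#' @export
srePipelineConfig <- function(annotation, fasta, expression, outDir,
                              sfExpression = NULL, sfMotifs = NULL,
                              tissues = NULL, minIntronLen = 400,
                              regionLen = 200, exonCap = 200,
                              rpkmThreshold = 3, clipEpsilon = 0.01,
                              screenAlpha = 0.05, coocAlpha = 0.05,
                              minPresence = 0.01, cvFolds = 100,
                              rcvRepeats = 100, rcvCvFolds = 10,
                              rcvScreenAlpha = 0.001,
                              fdr = 0.05, seed = 1) {
    cfg <- as.list(environment())
    stopifnot(rpkmThreshold >= 0, clipEpsilon > 0, clipEpsilon < 0.5,
              screenAlpha > 0, screenAlpha < 1, fdr > 0, fdr < 1,
              minPresence >= 0, minPresence <= 1, minIntronLen >= 0,
              cvFolds >= 2, rcvRepeats >= 1)
    cfg
}

#' Run the file-based SRE inference pipeline
#'
#' End-to-end run over all tissues: ASE selection from annotation,
#' inclusion ratios and gene-expression filtering, centered logit
#' responses, region extraction and feature-matrix construction, and the
#' four-stage inference per tissue. Writes the ASE table, response table,
#' per-feature results table and a per-tissue summary (number of ASEs,
#' SREs, pairs and percent variance explained) into \code{outDir}.
#'
#' @param config a list from \code{\link{srePipelineConfig}}.
#' @return list with \code{fits} (per-tissue \code{\link{SreFit}}s),
#'   \code{summary} (data.frame), \code{ases}, \code{regions},
#'   \code{response}.
#' @export
runSrePipeline <- function(config) {
    message("resolved config: ",
            paste(names(config), vapply(config, function(x)
                paste(format(x), collapse = ","), character(1L)),
                sep = "=", collapse = "; "))
    genome <- loadGenome(config$fasta)
    models <- readGenePred(config$annotation, genome)
    ases <- selectCassetteExons(models,
                                minIntronLen = config$minIntronLen)
    if (length(asGRanges(ases)) == 0L)
        stop("no cassette exons passed the five selection criteria ",
             "(minIntronLen = ", config$minIntronLen, ")")
    expr <- readExpressionTable(config$expression)
    tissues <- config$tissues
    if (is.null(tissues)) tissues <- sort(unique(expr$tissue))
    ir <- inclusionRatioMatrix(ases, expr, tissues)
    keep <- filterByGeneExpression(ases, expr, config$rpkmThreshold,
                                   tissues)
    ir[!keep] <- NA_real_
    if (all(is.na(ir)))
        stop("no (ASE, tissue) pair passed the gene-expression filter ",
             "(> ", config$rpkmThreshold, " RPKM)")
    resp <- computeResponse(ir, clipEpsilon = config$clipEpsilon)
    regions <- extractRegions(ases, genome, regionLen = config$regionLen,
                              exonCap = config$exonCap)
    fm <- buildFeatureMatrix(regions, minPresence = config$minPresence)

    sfExprTab <- if (!is.null(config$sfExpression))
        read.delim(config$sfExpression, stringsAsFactors = FALSE)
    else NULL
    sfMotifTab <- if (!is.null(config$sfMotifs))
        read.delim(config$sfMotifs, stringsAsFactors = FALSE)
    else NULL

    y <- responses(resp)
    fits <- list()
    for (k in seq_along(tissues)) {
        t <- tissues[k]
        fits[[t]] <- fitSreModel(
            y[, t], fm, tissue = t,
            screenAlpha = config$screenAlpha,
            coocAlpha = config$coocAlpha,
            minPresence = config$minPresence,
            cvFolds = config$cvFolds, rcvRepeats = config$rcvRepeats,
            rcvCvFolds = config$rcvCvFolds,
            rcvScreenAlpha = config$rcvScreenAlpha, fdr = config$fdr,
            seed = config$seed + 17L * k,
            sfExpression = sfExprTab, sfMotifs = sfMotifTab)
    }
    summary <- data.frame(
        tissue = tissues,
        nAses = vapply(fits, function(f) f@n, integer(1L)),
        nSres = vapply(fits, function(f)
            sum(f@results$passesFdr & f@results$type == "SRE"),
            integer(1L)),
        nPairs = vapply(fits, function(f)
            sum(f@results$passesFdr & f@results$type == "pair"),
            integer(1L)),
        r2 = vapply(fits, function(f) f@r2, numeric(1L)),
        row.names = NULL)
    if (!is.null(config$outDir)) {
        dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
        writeAseTable(ases, file.path(config$outDir, "ases.tsv"))
        writeResponseTable(resp, file.path(config$outDir, "response.tsv"))
        writeResultsTable(fits, file.path(config$outDir, "results.tsv"),
                          regions = regions)
        write.table(summary, file.path(config$outDir, "summary.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(fits = fits, summary = summary, ases = ases, regions = regions,
         response = resp)
}

#' Write the per-feature results table
#'
#' One row per selected SRE or SRE pair across tissues, mirroring the
#' shape of a supplementary results table: tissue, type, hexamers and
#' regions, coefficient, p-value, q-value, occurrence count, effect call
#' and region-pair class. Same-region pairs whose placements overlap by 5
#' nt in at least half of their co-occurrences are flagged as possibly
#' arising from a single motif longer than 6 nt (heuristic).
#'
#' @param fits an \code{\link{SreFit}} or list of them.
#' @param path output TSV path.
#' @param regions optional \code{\link{AseRegionSet}}; required for the
#'   long-motif flag (otherwise \code{NA}).
#' @return invisibly, the data.frame written.
#' @export
writeResultsTable <- function(fits, path, regions = NULL) {
    if (is(fits, "SreFit")) fits <- list(fits)
    rows <- lapply(fits, function(f) {
        res <- as.data.frame(modelResults(f))
        if (!nrow(res)) return(NULL)
        res$tissue <- f@tissue
        res
    })
    rows <- rows[!vapply(rows, is.null, logical(1L))]
    if (!length(rows)) {
        df <- data.frame(tissue = character(0), type = character(0),
                         hexamer1 = character(0), region1 = character(0),
                         hexamer2 = character(0), region2 = character(0),
                         coefficient = numeric(0), pValue = numeric(0),
                         qValue = numeric(0), occurrences = integer(0),
                         effect = character(0),
                         regionPairClass = character(0),
                         longMotifFlag = logical(0))
        write.table(df, path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        return(invisible(df))
    }
    df <- do.call(rbind, rows)
    df$regionPairClass <- ifelse(
        df$type == "pair",
        regionPairClass(df$region1,
                        ifelse(is.na(df$region2), df$region1,
                               df$region2)),
        NA_character_)
    df$longMotifFlag <- vapply(seq_len(nrow(df)), function(i) {
        if (df$type[i] != "pair" || is.na(df$region2[i]) ||
            df$region1[i] != df$region2[i]) return(NA)
        if (is.null(regions)) return(NA)
        longMotifFlag(df$hexamer1[i], df$hexamer2[i], df$region1[i],
                      regions)
    }, logical(1L))
    df <- df[, c("tissue", "type", "hexamer1", "region1", "hexamer2",
                 "region2", "coefficient", "pValue", "qValue",
                 "occurrences", "effect", "regionPairClass",
                 "longMotifFlag")]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}

## TRUE when, among ASEs carrying both hexamers in the region, at least
## half have occurrences exactly 1 nt apart (a 5-nt overlap, i.e. a 7-mer)
longMotifFlag <- function(hex1, hex2, region, regions, minFrac = 0.5) {
    seqs <- regionSeqs(regions)[[region]]
    m1 <- vmatchPattern(chartr("U", "T", hex1),
                        DNAStringSet(chartr("U", "T", as.character(seqs))))
    m2 <- vmatchPattern(chartr("U", "T", hex2),
                        DNAStringSet(chartr("U", "T", as.character(seqs))))
    both <- which(lengths(m1) > 0L & lengths(m2) > 0L)
    if (!length(both)) return(FALSE)
    overlapping <- vapply(both, function(i) {
        d <- outer(start(m1[[i]]), start(m2[[i]]), function(a, b)
            abs(a - b))
        any(d == 1L)
    }, logical(1L))
    mean(overlapping) >= minFrac
}
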