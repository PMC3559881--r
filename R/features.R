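#' @include AllClasses.R
NULL

#' The hexamer universe
#'
#' All \eqn{4^6 = 4096} hexamers over the RNA alphabet, in lexicographic
#' order. Together with the five region labels this defines the
#' 20480-column feature universe; a feature column is keyed as
#' \code{"HEXAMER:REGION"} and a pair column as the \code{"|"}-joined keys
#' of its parents.
#'
#' @return character vector of 4096 hexamers.
#' @export
hexamerUniverse <- function() {
    g <- expand.grid(RNA_BASES, RNA_BASES, RNA_BASES,
                     RNA_BASES, RNA_BASES, RNA_BASES,
                     stringsAsFactors = FALSE)[, 6:1]
    sort(do.call(paste0, g))
}

#' Hexamers present in an RNA sequence
#'
#' Enumerates all length-6 windows of a sequence; windows containing
#' \code{N} (masked positions) contribute nothing. Presence is recorded as
#' a set, not as occurrence counts.
#'
#' @param seq a single RNA sequence (character, alphabet A/C/G/U/N).
#' @return character vector of the distinct hexamers present (empty for
#'   sequences shorter than 6 nt).
#' @examples
#' hexamersInSequence("UGCAUGU")   # UGCAUG, GCAUGU
#' @export
hexamersInSequence <- function(seq) {
    stopifnot(is.character(seq), length(seq) == 1L)
    seq <- toupper(seq)
    n <- nchar(seq)
    if (n < 6L) return(character(0))
    if (grepl("[^ACGUN]", seq))
        stop("sequence contains characters outside A/C/G/U/N")
    w <- substring(seq, seq_len(n - 5L), seq_len(n - 5L) + 5L)
    unique(w[!grepl("N", w, fixed = TRUE)])
}

#' Build the binary hexamer-by-region feature matrix
#'
#' One row per ASE, one column per (hexamer, region) with at least
#' \code{minPresence} presence across ASEs. Entry (i, k) is 1 iff hexamer k
#' occurs anywhere in region k of ASE i (presence, not count; occurrence
#' counts enter reports as metadata only). The same hexamer in two regions
#' gives two distinct columns.
#'
#' @param regionSet an \code{\link{AseRegionSet}}.
#' @param minPresence minimum fraction of ASEs a column must be present in
#'   (default 1\%); lower-presence columns are dropped and counted in
#'   \code{metadata(featureInfo(.))$droppedLowPresence}.
#' @return a \code{\link{SpliceFeatureMatrix}} of main-effect columns.
#' @export
buildFeatureMatrix <- function(regionSet, minPresence = 0.01) {
    stopifnot(is(regionSet, "AseRegionSet"))
    n <- length(aseIds(regionSet))
    if (n < 1L) stop("at least one ASE is required")
    mats <- list()
    for (r in REGION_LABELS) {
        counts <- oligonucleotideFrequency(regionSeqs(regionSet)[[r]],
                                           width = 6L)
        ## Biostrings counts DNA-alphabet oligos for RNA input too; force
        ## the RNA spelling on the column names
        colnames(counts) <- chartr("T", "U", colnames(counts))
        pres <- counts > 0L
        colnames(pres) <- paste0(colnames(counts), ":", r)
        mats[[r]] <- pres
    }
    full <- do.call(cbind, mats)
    presence <- colMeans(full)
    keep <- presence >= minPresence
    dropped <- sum(!keep)
    mat <- methods::as(methods::as(Matrix::Matrix(full[, keep,
                                                       drop = FALSE],
                                                  sparse = TRUE),
                                   "generalMatrix"), "CsparseMatrix")
    mat <- 1 * (mat != 0)
    rownames(mat) <- aseIds(regionSet)
    keys <- colnames(mat)
    hex <- sub(":.*$", "", keys)
    reg <- sub("^.*:", "", keys)
    info <- DataFrame(type = rep("SRE", ncol(mat)),
                      hexamer1 = hex, region1 = reg,
                      hexamer2 = NA_character_, region2 = NA_character_,
                      parent1 = NA_character_, parent2 = NA_character_,
                      presence = presence[keep], row.names = keys)
    metadata(info)$droppedLowPresence <- dropped
    new("SpliceFeatureMatrix", mat = mat, info = info)
}

#' Classify a region pair
#'
#' Any pair of the five regions falls into one of 15 unordered classes
#' (5 same-region + 10 cross-region), e.g. \code{"UD-DU"} for exon
#' definition or \code{"UU-UD"} for intron definition.
#'
#' @param region1,region2 region labels.
#' @return character label of the unordered region pair.
#' @export
regionPairClass <- function(region1, region2) {
    if (!all(c(region1, region2) %in% REGION_LABELS))
        stop("region labels must be among: ",
             paste(REGION_LABELS, collapse = ", "))
    mapply(function(a, b) {
        paste(c(a, b)[order(match(c(a, b), REGION_LABELS))],
              collapse = "-")
    }, region1, region2, USE.NAMES = FALSE)
}

#' Append pairwise product columns to a feature matrix
#'
#' Each pair column is the elementwise product (logical AND) of two parent
#' main-effect columns and carries the cooperative-interaction term of the
#' model. Pairs may combine two regions or the same region (a same-region
#' pair can arise from a single motif longer than 6 nt).
#'
#' @param fm a \code{\link{SpliceFeatureMatrix}} of main-effect columns.
#' @param pairs two-column matrix (or data.frame) of parent column names
#'   (keys \code{"HEXAMER:REGION"}) or column indices.
#' @param minPresence product columns present in fewer than this fraction
#'   of ASEs are dropped.
#' @return a \code{\link{SpliceFeatureMatrix}} with the surviving product
#'   columns appended after the mains.
#' @export
buildPairColumns <- function(fm, pairs, minPresence = 0.01) {
    stopifnot(is(fm, "SpliceFeatureMatrix"))
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L) stop("pairs must have two columns")
    if (nrow(pairs) == 0L) return(fm)
    mat <- designMatrix(fm)
    toIdx <- function(p) {
        if (is.numeric(p)) {
            if (any(p < 1 | p > ncol(mat)))
                stop("pair references a column outside the matrix")
            as.integer(p)
        } else {
            i <- match(p, colnames(mat))
            if (anyNA(i))
                stop("pair references absent (dropped?) parent column(s): ",
                     paste(unique(p[is.na(i)]), collapse = ", "))
            i
        }
    }
    i1 <- toIdx(pairs[, 1L]); i2 <- toIdx(pairs[, 2L])
    if (any(i1 == i2)) stop("a pair must have two distinct parents")
    prod <- mat[, i1, drop = FALSE] * mat[, i2, drop = FALSE]
    presence <- Matrix::colSums(prod) / nrow(mat)
    keep <- presence >= minPresence
    if (!any(keep)) return(fm)
    prod <- prod[, keep, drop = FALSE]
    i1 <- i1[keep]; i2 <- i2[keep]
    info <- featureInfo(fm)
    k1 <- colnames(mat)[i1]; k2 <- colnames(mat)[i2]
    colnames(prod) <- paste0(k1, "|", k2)
    pinfo <- DataFrame(type = rep("pair", length(i1)),
                       hexamer1 = info$hexamer1[i1],
                       region1 = info$region1[i1],
                       hexamer2 = info$hexamer1[i2],
                       region2 = info$region1[i2],
                       parent1 = k1, parent2 = k2,
                       presence = presence[keep],
                       row.names = colnames(prod))
    dup <- duplicated(colnames(prod))
    newMat <- cbind(mat, prod[, !dup, drop = FALSE])
    newInfo <- rbind(info, pinfo[!dup, ])
    metadata(newInfo) <- metadata(info)
    new("SpliceFeatureMatrix",
        mat = methods::as(newMat, "CsparseMatrix"), info = newInfo)
}

#' Wrap a plain 0/1 matrix as a feature matrix
#'
#' Convenience constructor for simulation studies and tests: columns named
#' \code{"HEXAMER:REGION"} become main-effect columns.
#'
#' @param mat numeric or logical 0/1 matrix; row names are ASE ids and
#'   column names feature keys (defaults are generated when absent).
#' @return a \code{\link{SpliceFeatureMatrix}}.
#' @export
asFeatureMatrix <- function(mat) {
    mat <- methods::as(Matrix::Matrix(mat, sparse = TRUE),
                       "CsparseMatrix")
    mat <- 1 * (mat != 0)
    if (is.null(colnames(mat)))
        colnames(mat) <- sprintf("HEX%04d:UU", seq_len(ncol(mat)))
    if (is.null(rownames(mat)))
        rownames(mat) <- sprintf("ase%04d", seq_len(nrow(mat)))
    info <- DataFrame(type = rep("SRE", ncol(mat)),
                      hexamer1 = sub(":.*", "", colnames(mat)),
                      region1 = sub(".*:", "", colnames(mat)),
                      hexamer2 = NA_character_, region2 = NA_character_,
                      parent1 = NA_character_, parent2 = NA_character_,
                      presence = Matrix::colSums(mat) / nrow(mat),
                      row.names = colnames(mat))
    new("SpliceFeatureMatrix", mat = mat, info = info)
}

#' Subset a feature matrix by column keys
#'
#' @param fm a \code{\link{SpliceFeatureMatrix}}.
#' @param keys column names or indices to keep, in order.
#' @return the subsetted \code{SpliceFeatureMatrix}.
#' @export
subsetFeatures <- function(fm, keys) {
    mat <- designMatrix(fm)[, keys, drop = FALSE]
    info <- featureInfo(fm)[keys, ]
    new("SpliceFeatureMatrix", mat = mat, info = info)
}

#' Serialize a feature matrix to MatrixMarket + metadata TSV
#'
#' @param fm a \code{\link{SpliceFeatureMatrix}}.
#' @param prefix file prefix; writes \code{<prefix>.mtx},
#'   \code{<prefix>.columns.tsv} and \code{<prefix>.rows.tsv}.
#' @return invisibly, the paths written.
#' @export
writeFeatureMatrix <- function(fm, prefix) {
    mtx <- paste0(prefix, ".mtx")
    Matrix::writeMM(designMatrix(fm), mtx)
    cols <- paste0(prefix, ".columns.tsv")
    write.table(as.data.frame(featureInfo(fm)), cols, sep = "\t",
                quote = FALSE, row.names = TRUE)
    rows <- paste0(prefix, ".rows.tsv")
    write.table(data.frame(aseId = rownames(designMatrix(fm))), rows,
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(mtx, cols, rows))
}
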