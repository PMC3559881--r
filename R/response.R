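#' @include AllClasses.R
NULL

checkExprTable <- function(expr) {
    need <- c("isoformId", "geneId", "tissue", "expression")
    if (!all(need %in% colnames(expr)))
        stop("expression table must have columns: ",
             paste(need, collapse = ", "))
    if (anyDuplicated(expr[, c("isoformId", "tissue")]))
        stop("duplicate (isoformId, tissue) rows in expression table")
    if (any(!is.finite(expr$expression)) || any(expr$expression < 0))
        stop("expression values must be finite and non-negative")
    invisible(TRUE)
}

#' Read an isoform expression table
#'
#' TSV with columns isoformId, geneId, tissue, expression (RPKM).
#'
#' @param path path to the TSV file.
#' @return a validated data.frame.
#' @export
readExpressionTable <- function(path) {
    expr <- read.delim(path, stringsAsFactors = FALSE)
    checkExprTable(expr)
    expr
}

#' Inclusion ratio of a cassette exon in one tissue
#'
#' The fraction of the gene's expression carried by isoforms that include
#' the ASE: \eqn{IR = N_1 / (N_1 + N_2)} where \eqn{N_1} and \eqn{N_2} sum
#' the expression of the including and excluding isoforms.
#'
#' @param expr expression table (data.frame with isoformId, geneId, tissue,
#'   expression).
#' @param including,excluding character vectors of isoform ids.
#' @param tissue tissue label.
#' @return the inclusion ratio in [0, 1]; error if the total expression of
#'   both isoform sets is zero (the ASE is dropped for that tissue).
#' @examples
#' expr <- data.frame(isoformId = c("a", "b"), geneId = "g",
#'                    tissue = "heart", expression = c(3, 1))
#' inclusionRatio(expr, "a", "b", "heart")   # 0.75
#' @export
inclusionRatio <- function(expr, including, excluding, tissue) {
    checkExprTable(expr)
    sub <- expr[expr$tissue == tissue, ]
    n1 <- sum(sub$expression[sub$isoformId %in% including])
    n2 <- sum(sub$expression[sub$isoformId %in% excluding])
    if (n1 + n2 == 0)
        stop("total isoform expression is zero in tissue '", tissue, "'")
    n1 / (n1 + n2)
}

#' Inclusion-ratio matrix for a set of ASEs
#'
#' Applies \code{\link{inclusionRatio}} over all (ASE, tissue) pairs;
#' pairs with zero total expression become \code{NA}.
#'
#' @param ases a \code{\link{CassetteExons}} object.
#' @param expr expression table.
#' @param tissues tissue labels (default: all tissues in \code{expr}).
#' @return numeric matrix (ASE x tissue) of inclusion ratios with NAs for
#'   unmeasurable pairs.
#' @export
inclusionRatioMatrix <- function(ases, expr, tissues = NULL) {
    checkExprTable(expr)
    if (is.null(tissues)) tissues <- sort(unique(expr$tissue))
    gr <- asGRanges(ases)
    mc <- mcols(gr)
    ir <- matrix(NA_real_, length(gr), length(tissues),
                 dimnames = list(mc$aseId, tissues))
    for (t in tissues) {
        sub <- expr[expr$tissue == t, ]
        e <- setNames(sub$expression, sub$isoformId)
        for (i in seq_along(gr)) {
            n1 <- sum(e[intersect(names(e), mc$includingTx[[i]])])
            n2 <- sum(e[intersect(names(e), mc$excludingTx[[i]])])
            if (n1 + n2 > 0) ir[i, t] <- n1 / (n1 + n2)
        }
    }
    ir
}

#' Filter (ASE, tissue) pairs by gene expression
#'
#' A pair is retained only when the summed expression of all the gene's
#' isoforms in that tissue is strictly greater than \code{threshold} RPKM,
#' ensuring a reliable inclusion-ratio estimate.
#'
#' @param ases a \code{\link{CassetteExons}} object.
#' @param expr expression table.
#' @param threshold RPKM threshold (strict inequality).
#' @param tissues tissue labels (default: all in \code{expr}).
#' @return logical matrix (ASE x tissue): TRUE where retained.
#' @export
filterByGeneExpression <- function(ases, expr, threshold = 3,
                                   tissues = NULL) {
    checkExprTable(expr)
    if (is.null(tissues)) tissues <- sort(unique(expr$tissue))
    mc <- mcols(asGRanges(ases))
    geneTissue <- tapply(expr$expression,
                         list(expr$geneId, expr$tissue), sum)
    keep <- matrix(FALSE, length(mc$aseId), length(tissues),
                   dimnames = list(mc$aseId, tissues))
    for (t in tissues) {
        if (!t %in% colnames(geneTissue)) next
        ge <- geneTissue[, t]
        idx <- match(mc$geneId, rownames(geneTissue))
        v <- ge[idx]
        keep[, t] <- !is.na(v) & v > threshold
    }
    keep
}

#' Centered logit response from an inclusion-ratio matrix
#'
#' Clips inclusion ratios into \eqn{[\epsilon, 1-\epsilon]} (boundary
#' values usually reflect low read abundance of the minor isoform), takes
#' the natural-log logit, and centers each ASE by the average over its
#' valid tissues, which serves as the reference:
#' \eqn{y_{ij} = \mathrm{logit}(IR_{ij}) - T^{-1} \sum_t \mathrm{logit}(IR_{it})}.
#' ASEs with fewer than two valid tissues are dropped (the reference is
#' undefined for a single tissue).
#'
#' @param ir numeric matrix (ASE x tissue) of inclusion ratios, NA where a
#'   pair was dropped by upstream filters.
#' @param clipEpsilon clipping constant in (0, 0.5).
#' @return a \code{\link{SplicingResponse}}.
#' @examples
#' ir <- rbind(ase1 = c(a = 0.8, b = 0.5, c = 0.2))
#' responses(computeResponse(ir))    # 1.386, 0, -1.386
#' @export
computeResponse <- function(ir, clipEpsilon = 0.01) {
    if (!is.matrix(ir)) stop("ir must be a matrix (ASEs x tissues)")
    if (clipEpsilon <= 0 || clipEpsilon >= 0.5)
        stop("clipEpsilon must be in (0, 0.5)")
    nValid <- rowSums(!is.na(ir))
    if (nrow(ir) == 1L && nValid < 2L)
        stop("at least two tissues with a valid inclusion ratio are ",
             "required; the cross-tissue reference is undefined otherwise")
    drop <- nValid < 2L
    ir2 <- ir
    ir2[drop, ] <- NA_real_
    clipped <- pmin(pmax(ir2, clipEpsilon), 1 - clipEpsilon)
    lg <- log(clipped / (1 - clipped))
    ref <- rowMeans(lg, na.rm = TRUE)
    ref[drop] <- NA_real_
    y <- lg - ref
    new("SplicingResponse", ir = ir2, y = y,
        clipEpsilon = clipEpsilon)
}

#' Effective exon length for unique-read counting
#'
#' Number of distinct read start positions that place a read of length
#' \code{r} fully inside an exon of length \code{l}, minus the \code{m}
#' positions where such a read maps to multiple genomic loci:
#' \eqn{\max(l - r + 1 - m, 0)}.
#'
#' @param l exon length (nt).
#' @param r read length (nt).
#' @param m number of multi-mappable read start positions.
#' @return effective length in nt; error when the exon is shorter than the
#'   read.
#' @examples
#' effectiveExonLength(100, 32)       # 69
#' effectiveExonLength(100, 32, 10)   # 59
#' @export
effectiveExonLength <- function(l, r, m = 0) {
    if (any(m < 0)) stop("m must be non-negative")
    if (any(l < r))
        stop("exon length must be at least the read length")
    pmax(l - r + 1 - m, 0)
}

#' Write a response table
#'
#' @param resp a \code{\link{SplicingResponse}}.
#' @param path output TSV path.
#' @return invisibly, the data.frame written (aseId, tissue, ir, y).
#' @export
writeResponseTable <- function(resp, path) {
    ir <- inclusionRatios(resp)
    y <- responses(resp)
    df <- data.frame(
        aseId = rep(rownames(ir), ncol(ir)),
        tissue = rep(colnames(ir), each = nrow(ir)),
        ir = as.vector(ir), y = as.vector(y))
    df <- df[!is.na(df$ir), ]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}
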