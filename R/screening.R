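#' @include features.R
NULL

#' Marginal screening of feature columns
#'
#' Stage-1 dimension reduction: each binary column is tested one at a time
#' with the simple linear regression \eqn{y = \beta_0 + \beta s + e}; the
#' two-sided t-test p-value on the slope decides whether the column enters
#' the retained set. The closed-form t statistic is used (identical to
#' \code{lm}), which makes screening the full 20480-column universe cheap.
#'
#' @param y numeric response vector (one tissue), length = rows of
#'   \code{fm}.
#' @param fm a \code{\link{SpliceFeatureMatrix}} (main-effect columns).
#' @param alpha retention threshold on the p-value (kept iff p < alpha).
#' @return \code{DataFrame} with one row per column: \code{key},
#'   \code{slope}, \code{tStat}, \code{pValue}, \code{kept},
#'   \code{reason} (NA when tested; "constant" for untestable columns).
#' @export
marginalScreen <- function(y, fm, alpha = 0.05) {
    mat <- designMatrix(fm)
    n <- nrow(mat)
    if (length(y) != n) stop("length(y) must equal nrow(fm)")
    if (n < 3L) stop("at least 3 observations are required")
    if (any(!is.finite(y))) stop("y must be finite")
    n1 <- Matrix::colSums(mat)
    sy <- sum(y)
    syy <- sum(y^2)
    sxy <- as.vector(Matrix::crossprod(mat, y))
    sxx <- n1 - n1^2 / n
    constant <- n1 == 0 | n1 == n
    slope <- rep(NA_real_, ncol(mat))
    tStat <- rep(NA_real_, ncol(mat))
    p <- rep(NA_real_, ncol(mat))
    idx <- which(!constant)
    if (length(idx)) {
        sxyC <- sxy[idx] - n1[idx] * sy / n
        b <- sxyC / sxx[idx]
        rss <- pmax(syy - sy^2 / n - b * sxyC, 0)
        s2 <- rss / (n - 2L)
        se <- sqrt(s2 / sxx[idx])
        tv <- ifelse(se > 0, b / se, Inf * sign(b))
        slope[idx] <- b
        tStat[idx] <- tv
        p[idx] <- 2 * pt(-abs(tv), n - 2L)
    }
    kept <- unname(!constant & !is.na(p) & p < alpha)
    DataFrame(key = colnames(mat), slope = unname(slope),
              tStat = unname(tStat), pValue = unname(p), kept = kept,
              reason = unname(ifelse(constant, "constant",
                                     ifelse(kept, NA_character_,
                                            "not significant"))),
              row.names = colnames(mat))
}

## fast index-only marginal screen on a plain (sparse) matrix; used by
## rcvVariance to re-screen within a half-sample
marginalScreenIdx <- function(X, y, alpha = 0.05) {
    n <- nrow(X)
    xbar <- Matrix::colSums(X) / n
    sxy <- as.vector(Matrix::crossprod(X, y)) - n * xbar * mean(y)
    sxx <- as.vector(Matrix::colSums(X^2)) - n * xbar^2
    ok <- sxx > 0
    p <- rep(1, ncol(X))
    b <- sxy[ok] / sxx[ok]
    rss <- pmax(sum((y - mean(y))^2) - b * sxy[ok], 0)
    tv <- b / sqrt(rss / (n - 2L) / sxx[ok])
    p[ok] <- 2 * pt(-abs(tv), n - 2L)
    which(p < alpha)
}

#' Hypergeometric co-occurrence test
#'
#' One-sided (over-representation) test of the null hypothesis that the
#' presence of one hexamer is independent of the presence of the other:
#' \eqn{P(X \ge \mathrm{overlap})} for a hypergeometric draw of
#' \eqn{|s_j|} from a population of \eqn{n} with \eqn{|s_i|} successes.
#'
#' @param si,sj binary (0/1 or logical) vectors of equal length.
#' @return the one-sided p-value.
#' @examples
#' cooccurrenceTest(rep(1:0, each = 5), rep(1:0, each = 5)) # 1/choose(10,5)
#' @export
cooccurrenceTest <- function(si, sj) {
    si <- as.numeric(si); sj <- as.numeric(sj)
    if (length(si) != length(sj))
        stop("si and sj must have equal length")
    if (!all(si %in% c(0, 1)) || !all(sj %in% c(0, 1)))
        stop("si and sj must be binary")
    n <- length(si)
    k <- sum(si); d <- sum(sj); ov <- sum(si * sj)
    phyper(ov - 1, k, n - k, d, lower.tail = FALSE)
}

#' Interaction screening of feature pairs
#'
#' Stage-1 screening of cooperative pairs. For each unordered pair of
#' retained main-effect columns, the product term is tested in
#' \eqn{y = \beta_0 + \beta_i s_i + \beta_j s_j + \gamma s_i s_j + e}
#' (closed-form OLS on the saturated 2x2 cell-mean design, identical to
#' \code{lm}). A pair is kept only when the product-term p-value is below
#' \code{alpha}, the hypergeometric co-occurrence p-value is below
#' \code{coocAlpha}, and the product column is present in at least
#' \code{minPresence} of the ASEs. Pairs whose product coincides with a
#' parent (an empty design cell) are rank-deficient and dropped.
#'
#' @param y numeric response vector.
#' @param fm \code{\link{SpliceFeatureMatrix}} of main-effect columns.
#' @param retained character vector of column keys retained by
#'   \code{\link{marginalScreen}} (pairs are formed only among these).
#' @param alpha p-value threshold for the interaction term.
#' @param coocAlpha p-value threshold for the co-occurrence test.
#' @param minPresence minimum presence fraction of the product column.
#' @return \code{DataFrame}: \code{parent1}, \code{parent2},
#'   \code{estimate}, \code{pValue}, \code{coocPValue}, \code{presence},
#'   \code{kept}, \code{reason}.
#' @export
interactionScreen <- function(y, fm, retained, alpha = 0.05,
                              coocAlpha = 0.05, minPresence = 0.01) {
    mat <- designMatrix(fm)
    if (!all(retained %in% colnames(mat)))
        stop("retained keys absent from the feature matrix: ",
             paste(setdiff(retained, colnames(mat)), collapse = ", "))
    X <- mat[, retained, drop = FALSE]
    n <- nrow(X)
    p <- ncol(X)
    empty <- DataFrame(parent1 = character(0), parent2 = character(0),
                       estimate = numeric(0), pValue = numeric(0),
                       coocPValue = numeric(0), presence = numeric(0),
                       kept = logical(0), reason = character(0))
    if (p < 2L) return(empty)
    n1 <- Matrix::colSums(X)
    C <- as.matrix(Matrix::crossprod(X))                 # n11
    Cy <- as.matrix(Matrix::crossprod(X, X * y))         # sum y, both present
    sy <- as.vector(Matrix::crossprod(X, y))
    Sy <- sum(y); Sy2 <- sum(y^2)

    ut <- which(upper.tri(C), arr.ind = TRUE)
    i <- ut[, 1L]; j <- ut[, 2L]
    n11 <- C[ut]
    n10 <- n1[i] - n11
    n01 <- n1[j] - n11
    n00 <- n - n1[i] - n1[j] + n11
    s11 <- Cy[ut]
    s10 <- sy[i] - s11
    s01 <- sy[j] - s11
    s00 <- Sy - sy[i] - sy[j] + s11

    presence <- n11 / n
    coocP <- phyper(n11 - 1, n1[i], n - n1[i], n1[j], lower.tail = FALSE)

    degenerate <- n11 == n1[i] | n11 == n1[j] | n00 == 0
    zeroCooc <- n11 == 0
    lowPres <- presence < minPresence

    est <- rep(NA_real_, length(n11))
    pval <- rep(NA_real_, length(n11))
    testable <- !degenerate & !zeroCooc
    if (any(testable)) {
        k <- which(testable)
        cellFit <- s11[k]^2 / n11[k] + s10[k]^2 / n10[k] +
            s01[k]^2 / n01[k] + s00[k]^2 / n00[k]
        rss <- pmax(Sy2 - cellFit, 0)
        s2 <- rss / (n - 4L)
        est[k] <- s11[k] / n11[k] - s10[k] / n10[k] -
            s01[k] / n01[k] + s00[k] / n00[k]
        se <- sqrt(s2 * (1 / n11[k] + 1 / n10[k] + 1 / n01[k] +
                         1 / n00[k]))
        tv <- ifelse(se > 0, est[k] / se, Inf * sign(est[k]))
        pval[k] <- 2 * pt(-abs(tv), n - 4L)
    }
    kept <- testable & !lowPres & coocP < coocAlpha &
        !is.na(pval) & pval < alpha
    reason <- rep(NA_character_, length(n11))
    reason[!kept & zeroCooc] <- "zero co-occurrence"
    reason[!kept & !zeroCooc & degenerate] <- "collinear"
    reason[!kept & !degenerate & !zeroCooc & lowPres] <- "low presence"
    reason[!kept & is.na(reason) & coocP >= coocAlpha] <-
        "co-occurrence not significant"
    reason[!kept & is.na(reason)] <- "not significant"
    DataFrame(parent1 = retained[i], parent2 = retained[j],
              estimate = est, pValue = pval, coocPValue = coocP,
              presence = presence, kept = kept, reason = reason)
}

#' Overlap enrichment between two motif sets
#'
#' One-sided Fisher's exact test for enrichment of the overlap between two
#' k-mer sets drawn from a common universe (4096 for hexamers), used to
#' compare a discovered SRE set against an external motif collection.
#'
#' @param setA,setB sizes of the two sets.
#' @param overlap number of shared k-mers.
#' @param universe size of the k-mer universe.
#' @return the one-sided (greater) Fisher's exact p-value.
#' @examples
#' overlapEnrichment(854, 639, 180, 4096)   # ~9.4e-7
#' @export
overlapEnrichment <- function(setA, setB, overlap, universe = 4096) {
    v <- c(setA, setB, overlap, universe)
    if (any(v != round(v)) || any(v < 0))
        stop("counts must be non-negative integers")
    if (overlap > min(setA, setB))
        stop("overlap cannot exceed the smaller set")
    if (max(setA, setB) > universe || setA + setB - overlap > universe)
        stop("sets cannot exceed the universe")
    tab <- matrix(c(overlap, setA - overlap,
                    setB - overlap, universe - setA - setB + overlap),
                  nrow = 2L)
    fisher.test(tab, alternative = "greater")$p.value
}

#' Read a plain-text k-mer list
#'
#' One k-mer per line; comments (#) and blank lines are ignored; T is read
#' as U.
#'
#' @param path path to the list file.
#' @param k expected k-mer length (default 6; NULL to skip the check).
#' @return character vector of distinct upper-case RNA k-mers.
#' @export
readMotifList <- function(path, k = 6) {
    x <- trimws(readLines(path))
    x <- x[nzchar(x) & !startsWith(x, "#")]
    x <- unique(chartr("Tt", "Uu", toupper(x)))
    if (!is.null(k) && length(x) && any(nchar(x) != k))
        stop("motif list contains entries that are not ", k, "-mers")
    if (any(grepl("[^ACGU]", x)))
        stop("motif list contains non-ACGU characters")
    x
}

#' @describeIn overlapEnrichment convenience wrapper taking two k-mer
#'   lists (character vectors or file paths) instead of counts.
#' @param listA,listB k-mer vectors or paths to plain-text lists.
#' @export
overlapEnrichmentFromLists <- function(listA, listB, universe = 4096) {
    if (is.character(listA) && length(listA) == 1L && file.exists(listA))
        listA <- readMotifList(listA)
    if (is.character(listB) && length(listB) == 1L && file.exists(listB))
        listB <- readMotifList(listB)
    overlapEnrichment(length(listA), length(listB),
                      length(intersect(listA, listB)), universe)
}
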