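#' @include penalized.R
NULL

## OLS residual variance of y regressed on the given columns (plus
## intercept); collinear columns are dropped deterministically (first kept
## in column order, as lm's pivoting does).
olsResidVariance <- function(X, y, cols) {
    n <- length(y)
    if (!length(cols)) {
        return(sum((y - mean(y))^2) / (n - 1L))
    }
    Xs <- as.matrix(X[, cols, drop = FALSE])
    fit <- lm(y ~ Xs)
    df <- fit$df.residual
    if (df <= 0) return(NA_real_)
    sum(fit$residuals^2) / df
}

#' Refitted cross-validation estimate of the residual variance
#'
#' Estimates the noise variance of a sparse high-dimensional linear model
#' without the downward bias of post-selection refits on the same data. In
#' each repeat the n samples are split into two even halves; a Lasso (with
#' internal CV for its penalty, one-standard-error rule) selects a
#' variable set on the first half, a second Lasso restricted to that set
#' is CV-fit on the second half, and the OLS refit of the surviving set on
#' the second half yields one variance estimate; the roles are then
#' reversed for the second estimate. The repeat's value is the mean of the
#' two, and the final estimate averages over repeats. The conservative
#' 1-SE rule is used inside the halves because aggressive (CV-minimum)
#' selection re-absorbs noise into the refit and biases the variance
#' estimate downward.
#'
#' @param X design matrix (n x p), typically the screened feature columns.
#' @param y response vector.
#' @param repeats number of random splits (the framework default is 100).
#' @param seed integer seed controlling all splits and internal CV folds.
#' @param cvFolds folds for the internal penalty selection on each half.
#' @param screenAlpha marginal-screening level applied within the
#'   selection half before its Lasso (\code{NULL} to disable). Screening
#'   performed once on the full data leaks information about every
#'   sample's noise into the candidate set, which biases the refit-half
#'   variance downward; re-running the screen inside the selection half
#'   restores the independence between variable choice and the refit
#'   half that the split-half argument relies on. On matrices that were
#'   already screened on the full data, a much stricter level is needed
#'   (the pipeline uses 0.001) so that passing the per-half screen
#'   reflects signal rather than the earlier global selection.
#' @return an \code{\link{RcvEstimate}}. Halves where the selected set is
#'   as large as the half-sample are skipped with a warning.
#' @export
rcvVariance <- function(X, y, repeats = 100, seed = 1, cvFolds = 10,
                        screenAlpha = 0.05) {
    X <- as(X, "CsparseMatrix")
    n <- nrow(X)
    if (n < 20L) stop("at least 20 samples are required for RCV")
    if (length(y) != n) stop("length(y) must equal nrow(X)")
    perRepeat <- matrix(NA_real_, repeats, 2L)
    set.seed(seed)
    seeds <- sample.int(.Machine$integer.max, repeats * 3L)
    nSkipped <- 0L
    for (r in seq_len(repeats)) {
        set.seed(seeds[3L * r - 2L])
        half1 <- sort(sample.int(n, n %/% 2L))
        half2 <- setdiff(seq_len(n), half1)
        halves <- list(c(1L, 2L), c(2L, 1L))
        parts <- list(half1, half2)
        for (h in 1:2) {
            sel <- parts[[halves[[h]][1L]]]
            ref <- parts[[halves[[h]][2L]]]
            est <- tryCatch({
                cand <- seq_len(ncol(X))
                if (!is.null(screenAlpha))
                    cand <- marginalScreenIdx(X[sel, , drop = FALSE],
                                              y[sel], screenAlpha)
                if (length(cand) < 2L) {
                    vRef <- y[ref]
                    sum((vRef - mean(vRef))^2) / (length(vRef) - 1L)
                } else {
                cv1 <- cvSelectLambda(X[sel, cand, drop = FALSE], y[sel],
                                      folds = cvFolds,
                                      seed = seeds[3L * r - 2L + h],
                                      rule = "1se")
                m1 <- cand[which(cv1$betaMin != 0)]
                if (length(m1) == 1L) {
                    m2 <- m1   # glmnet needs >= 2 columns; keep the one
                } else if (length(m1)) {
                    cv2 <- cvSelectLambda(X[ref, m1, drop = FALSE],
                                          y[ref], folds = cvFolds,
                                          seed = seeds[3L * r - 2L + h] +
                                              1L, rule = "1se")
                    m2 <- m1[cv2$betaMin != 0]
                } else m2 <- integer(0)
                if (length(m2) >= length(ref) - 1L) {
                    nSkipped <- nSkipped + 1L
                    NA_real_
                } else {
                    olsResidVariance(X[ref, , drop = FALSE], y[ref], m2)
                }
                }
            }, error = function(e) NA_real_)
            perRepeat[r, h] <- est
        }
    }
    if (nSkipped > 0L)
        warning(nSkipped, " half-sample estimate(s) skipped: selected ",
                "set as large as the half-sample")
    sigma2 <- mean(rowMeans(perRepeat, na.rm = TRUE), na.rm = TRUE)
    new("RcvEstimate", sigma2 = sigma2, perRepeat = perRepeat,
        seed = as.integer(seed))
}

#' Choose the final penalty using the RCV variance
#'
#' For every penalty on the (adaptive) Lasso path, the selected variables
#' are OLS-refit and the residual variance recorded; duplicated variable
#' sets are refit once. The chosen model is the one with the smallest
#' refit variance that still exceeds the RCV estimate
#' \eqn{\hat\sigma^2_{RCV}} — smaller variances indicate overfitting
#' relative to the honest noise level. When every model's variance falls
#' below \eqn{\hat\sigma^2_{RCV}}, the model whose variance is closest to
#' it (the most penalized one) is chosen, with a warning.
#'
#' @param path a \code{\link{PenalizedPath}} (typically adaptive Lasso).
#' @param X design matrix the path was fit on.
#' @param y response vector.
#' @param sigma2Rcv the RCV variance estimate (scalar or
#'   \code{\link{RcvEstimate}}).
#' @return list with \code{lambda}, \code{selected} (column names),
#'   \code{residVariance}, \code{allVariances} (per grid point) and
#'   \code{note} (NA or the fallback warning text).
#' @export
selectFinalLambda <- function(path, X, y, sigma2Rcv) {
    stopifnot(is(path, "PenalizedPath"))
    if (is(sigma2Rcv, "RcvEstimate")) sigma2Rcv <- sigma2Rcv@sigma2
    X <- as(X, "CsparseMatrix")
    nl <- length(path@lambda)
    supports <- lapply(seq_len(nl), function(k)
        which(path@beta[, k] != 0))
    key <- vapply(supports, paste, character(1L), collapse = ",")
    vars <- rep(NA_real_, nl)
    for (k in seq_len(nl)) {
        j <- which(key == key[k])[1L]   # refit each distinct support once
        if (is.na(vars[j]))
            vars[j] <- olsResidVariance(X, y, supports[[j]])
        vars[k] <- vars[j]
    }
    note <- NA_character_
    ok <- which(!is.na(vars) & vars > sigma2Rcv)
    if (length(ok)) {
        k <- ok[which.min(vars[ok])]
    } else {
        k <- which.min(abs(vars - sigma2Rcv))
        note <- paste0("no model's refit variance exceeds sigma2_RCV (",
                       signif(sigma2Rcv, 4),
                       "); chose the closest (most penalized) model")
        warning(note)
    }
    list(lambda = path@lambda[k],
         selected = rownames(path@beta)[supports[[k]]],
         residVariance = vars[k], allVariances = vars, note = note)
}

#' Benjamini-Hochberg selection
#'
#' Step-up BH procedure at level \code{fdr}: with ordered p-values
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, find the largest k with
#' \eqn{p_{(k)} \le k \cdot fdr / m}; all hypotheses up to k pass.
#' Equivalent to \code{p.adjust(p, "BH") <= fdr}, which is how it is
#' computed.
#'
#' @param p numeric vector of p-values.
#' @param fdr target false discovery rate.
#' @return list with \code{pass} (logical, parallel to \code{p}) and
#'   \code{qValue} (BH-adjusted p-values).
#' @export
bhSelect <- function(p, fdr = 0.05) {
    q <- p.adjust(p, method = "BH")
    list(pass = !is.na(q) & q <= fdr, qValue = q)
}

#' Percentage of variance explained
#'
#' \eqn{R^2 = 100 (1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2)}.
#'
#' @param y observed responses.
#' @param yhat fitted values.
#' @return R-squared in percent (at most 100; negative when the fit is
#'   worse than the mean).
#' @examples
#' rSquared(c(1, 2, 3, 4), c(1.5, 1.5, 3.5, 3.5))  # 80
#' @export
rSquared <- function(y, yhat) {
    if (length(y) != length(yhat)) stop("y and yhat must have equal length")
    tss <- sum((y - mean(y))^2)
    if (tss == 0) stop("Var(y) is zero; R-squared is undefined")
    100 * (1 - sum((y - yhat)^2) / tss)
}

#' OLS refit with FDR control
#'
#' Refits the selected columns by ordinary least squares, computes
#' two-sided t-test p-values per coefficient, applies Benjamini-Hochberg
#' step-up at level \code{fdr}, and reports the percentage of variance
#' explained by the FDR-passing model. Collinear columns are dropped
#' deterministically (first kept in column order) and reported.
#'
#' @param X design matrix containing (at least) the selected columns.
#' @param y response vector.
#' @param selected column names (or indices) of the selected variables.
#' @param fdr target false discovery rate.
#' @return list with \code{table} (\code{DataFrame}: key, coefficient, se,
#'   pValue, qValue, passesFdr), \code{dropped} (collinear columns),
#'   \code{residVariance}, \code{r2} (percent, from the FDR-passing
#'   refit; \code{NA} when nothing passes and 0-variable models are
#'   reported as 0).
#' @export
olsRefitFdr <- function(X, y, selected, fdr = 0.05) {
    X <- as(X, "CsparseMatrix")
    if (is.numeric(selected)) selected <- colnames(X)[selected]
    n <- length(y)
    if (!length(selected)) {
        return(list(table = DataFrame(key = character(0),
                                      coefficient = numeric(0),
                                      se = numeric(0), pValue = numeric(0),
                                      qValue = numeric(0),
                                      passesFdr = logical(0)),
                    dropped = character(0),
                    residVariance = sum((y - mean(y))^2) / (n - 1L),
                    r2 = 0))
    }
    if (n <= length(selected))
        stop("more selected columns than observations")
    Xs <- as.matrix(X[, selected, drop = FALSE])
    colnames(Xs) <- selected
    fit <- lm(y ~ Xs)
    cf <- summary(fit)$coefficients
    est <- coef(fit)[-1L]
    dropped <- selected[is.na(est)]
    kept <- selected[!is.na(est)]
    rows <- match(paste0("Xs", kept), rownames(cf))
    pvals <- unname(cf[rows, "Pr(>|t|)"])
    pvals[!is.finite(pvals)] <- NA_real_
    bh <- bhSelect(pvals, fdr)
    tab <- DataFrame(key = kept,
                     coefficient = unname(cf[rows, "Estimate"]),
                     se = unname(cf[rows, "Std. Error"]),
                     pValue = pvals, qValue = bh$qValue,
                     passesFdr = bh$pass, row.names = kept)
    pass <- kept[bh$pass]
    if (length(pass)) {
        finalFit <- lm(y ~ as.matrix(X[, pass, drop = FALSE]))
        r2 <- rSquared(y, fitted(finalFit))
    } else {
        r2 <- 0
    }
    list(table = tab, dropped = dropped,
         residVariance = sum(fit$residuals^2) / fit$df.residual,
         r2 = r2)
}
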