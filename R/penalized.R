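#' @include AllClasses.R
NULL

## glmnet solves exactly the objective used here:
## (2n)^-1 ||y - b0 - X b||^2 + lambda ||b||_1, intercept unpenalized,
## coordinate descent with warm starts along a descending lambda grid.

## Largest penalty with a nonzero solution (KKT bound), computed on the
## same column scale the solver sees.
lambdaMaxKkt <- function(X, y, standardize = TRUE) {
    n <- nrow(X)
    yc <- y - mean(y)
    g <- as.vector(Matrix::crossprod(X, yc)) / n
    xbar <- Matrix::colSums(X) / n
    ## columns are centered implicitly by the intercept
    g <- g - xbar * mean(yc)
    if (standardize) {
        x2 <- as.vector(Matrix::colSums(X^2)) / n
        sdn <- sqrt(pmax(x2 - xbar^2, 0))
        ok <- sdn > 0
        g[ok] <- g[ok] / sdn[ok]
        g[!ok] <- 0
    }
    max(abs(g))
}

#' Lasso solution path
#'
#' Solves \eqn{\min_{\beta_0,\beta} (2n)^{-1}\|y - \beta_0 - X\beta\|^2 +
#' \lambda\|\beta\|_1} over a descending penalty grid by coordinate descent
#' (via glmnet), with warm starts and an unpenalized intercept. When
#' \code{lambdas} is not given, a grid of \code{nlambda} log-spaced values
#' from the KKT bound \eqn{\lambda_{max}} down to
#' \eqn{10^{-4}\lambda_{max}} is used.
#'
#' @param X numeric matrix or \code{dgCMatrix} (n x p).
#' @param y numeric response, length n.
#' @param lambdas optional penalty grid (sorted descending internally).
#' @param nlambda,lambdaMinRatio grid size and ratio of smallest to largest
#'   lambda for the automatic grid.
#' @param standardize standardize columns internally for the solver;
#'   coefficients are always reported on the original scale.
#' @param thresh coordinate-descent convergence threshold.
#' @param penaltyScale optional positive per-column scale: column j is
#'   divided by \code{penaltyScale[j]} before solving and the coefficient
#'   multiplied back, which turns the plain Lasso into a weighted one
#'   (used by \code{\link{adaptiveLassoPath}}).
#' @return a \code{\link{PenalizedPath}}.
#' @export
lassoPath <- function(X, y, lambdas = NULL, nlambda = 100,
                      lambdaMinRatio = 1e-4, standardize = TRUE,
                      thresh = 1e-7, penaltyScale = NULL) {
    X <- as(X, "CsparseMatrix")
    if (any(!is.finite(y)) || any(!is.finite(X@x)))
        stop("X and y must be finite")
    if (nrow(X) < 2L) stop("at least two observations are required")
    if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
    if (!is.null(penaltyScale)) {
        stopifnot(length(penaltyScale) == ncol(X), all(penaltyScale > 0))
        X <- X %*% Matrix::Diagonal(x = 1 / penaltyScale)
        colnames(X) <- names(penaltyScale)
    }
    if (is.null(lambdas)) {
        lmax <- lambdaMaxKkt(X, y, standardize)
        if (lmax == 0) lmax <- 1e-3
        lambdas <- exp(seq(log(lmax), log(lmax * lambdaMinRatio),
                           length.out = nlambda))
    }
    lambdas <- sort(unique(lambdas), decreasing = TRUE)
    fit <- glmnet(X, y, family = "gaussian", lambda = lambdas,
                  standardize = standardize, thresh = thresh,
                  maxit = 10^6)
    beta <- as(fit$beta, "CsparseMatrix")
    if (!is.null(penaltyScale))
        beta <- Matrix::Diagonal(x = 1 / penaltyScale) %*% beta
    beta <- as(beta, "CsparseMatrix")
    rownames(beta) <- colnames(X)
    new("PenalizedPath", lambda = as.numeric(fit$lambda),
        a0 = as.numeric(fit$a0), beta = beta,
        meta = list(standardize = standardize,
                    penaltyScale = penaltyScale, npasses = fit$npasses))
}

#' Coefficients of a path at one penalty
#'
#' @param path a \code{\link{PenalizedPath}}.
#' @param lambda penalty value; the closest grid point is used.
#' @return list with \code{a0}, \code{beta} (named numeric vector) and the
#'   grid \code{lambda} actually used.
#' @export
coefAt <- function(path, lambda) {
    k <- which.min(abs(path@lambda - lambda))
    list(a0 = path@a0[k],
         beta = setNames(as.numeric(path@beta[, k]),
                         rownames(path@beta)),
         lambda = path@lambda[k])
}

#' Select the Lasso penalty by cross-validation
#'
#' K-fold cross-validation on the mean squared prediction error; folds are
#' assigned by a seeded permutation so the result is deterministic given
#' the seed. \eqn{\lambda^*} is the grid value attaining the minimum CV
#' error. When \code{folds > n} the fold count falls back to \code{n}
#' (leave-one-out) with a warning.
#'
#' @inheritParams lassoPath
#' @param folds number of CV folds (the framework default is 100).
#' @param seed integer seed for the fold assignment.
#' @param rule \code{"min"} (default): \eqn{\lambda^*} attains the minimum
#'   CV error; \code{"1se"}: the sparsest model within one standard error
#'   of the minimum (used inside \code{\link{rcvVariance}}, where
#'   conservative selection keeps the variance estimate honest).
#' @return list with \code{lambda} (grid), \code{cvm}, \code{cvsd},
#'   \code{lambdaMin}, \code{folds}, \code{seed}, \code{path} (the
#'   full-data \code{\link{PenalizedPath}}) and \code{betaMin} (full-data
#'   coefficients at \code{lambdaMin}).
#' @export
cvSelectLambda <- function(X, y, folds = 100, seed = 1, lambdas = NULL,
                           standardize = TRUE, thresh = 1e-7,
                           penaltyScale = NULL, rule = c("min", "1se")) {
    rule <- match.arg(rule)
    X <- as(X, "CsparseMatrix")
    n <- nrow(X)
    if (folds < 2L) stop("at least 2 folds are required")
    if (folds > n) {
        warning("folds > n; falling back to ", n, "-fold (leave-one-out)")
        folds <- n
    }
    if (!is.null(penaltyScale)) {
        stopifnot(length(penaltyScale) == ncol(X), all(penaltyScale > 0))
        Xs <- X %*% Matrix::Diagonal(x = 1 / penaltyScale)
        colnames(Xs) <- colnames(X)
    } else Xs <- X
    if (is.null(lambdas)) {
        lmax <- lambdaMaxKkt(Xs, y, standardize)
        if (lmax == 0) lmax <- 1e-3
        lambdas <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 100))
    }
    lambdas <- sort(unique(lambdas), decreasing = TRUE)
    set.seed(seed)
    foldid <- sample(rep(seq_len(folds), length.out = n))
    cv <- cv.glmnet(Xs, y, lambda = lambdas, foldid = foldid,
                    standardize = standardize, thresh = thresh,
                    family = "gaussian", grouped = folds < n)
    path <- lassoPath(X, y, lambdas = lambdas, standardize = standardize,
                      thresh = thresh, penaltyScale = penaltyScale)
    lambdaSel <- if (rule == "min") cv$lambda.min else cv$lambda.1se
    sel <- coefAt(path, lambdaSel)
    list(lambda = as.numeric(cv$lambda), cvm = as.numeric(cv$cvm),
         cvsd = as.numeric(cv$cvsd), lambdaMin = as.numeric(lambdaSel),
         folds = folds, seed = seed, path = path, betaMin = sel$beta,
         a0Min = sel$a0)
}

#' Adaptive Lasso solution path
#'
#' Solves the adaptive Lasso \eqn{\min (2n)^{-1}\|y - \beta_0 - X\beta\|^2
#' + \lambda\sum_j w_j|\beta_j|} with weights
#' \eqn{w_j = 1/|\hat\beta_{lasso,j}|} taken from a first-stage (CV-selected)
#' Lasso fit. Variables with a zero first-stage coefficient have infinite
#' weight and are excluded; the problem is solved as a plain Lasso on the
#' rescaled columns \eqn{X_j |\hat\beta_j|} and coefficients are mapped
#' back to the original scale. The rescaled columns are not re-standardized
#' (the weights define the scale).
#'
#' @inheritParams lassoPath
#' @param lassoCoefs named numeric vector of first-stage Lasso
#'   coefficients (typically \code{betaMin} from
#'   \code{\link{cvSelectLambda}}).
#' @return a \code{\link{PenalizedPath}} over all original columns
#'   (structural zeros for excluded variables); when every first-stage
#'   coefficient is zero, an empty single-point path with a warning.
#' @export
adaptiveLassoPath <- function(X, y, lassoCoefs, lambdas = NULL,
                              nlambda = 100, lambdaMinRatio = 1e-4,
                              thresh = 1e-7) {
    X <- as(X, "CsparseMatrix")
    stopifnot(length(lassoCoefs) == ncol(X))
    nz <- which(lassoCoefs != 0)
    p <- ncol(X)
    if (!length(nz)) {
        warning("all first-stage Lasso coefficients are zero; ",
                "returning an empty model")
        beta <- as(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                        x = numeric(0), dims = c(p, 1L)),
                   "CsparseMatrix")
        rownames(beta) <- colnames(X)
        return(new("PenalizedPath", lambda = 1, a0 = mean(y), beta = beta,
                   meta = list(empty = TRUE)))
    }
    scale <- 1 / abs(lassoCoefs[nz])
    sub <- lassoPath(X[, nz, drop = FALSE], y, lambdas = lambdas,
                     nlambda = nlambda, lambdaMinRatio = lambdaMinRatio,
                     standardize = FALSE, thresh = thresh,
                     penaltyScale = setNames(scale, colnames(X)[nz]))
    subB <- Matrix::drop0(sub@beta)
    ## embed the nz-row submatrix back into the full p rows
    beta <- Matrix::sparseMatrix(i = nz[subB@i + 1L], p = subB@p,
                                 x = subB@x,
                                 dims = c(p, length(sub@lambda)),
                                 index1 = TRUE)
    beta <- as(beta, "CsparseMatrix")
    rownames(beta) <- colnames(X)
    new("PenalizedPath", lambda = sub@lambda, a0 = sub@a0, beta = beta,
        meta = c(sub@meta, list(firstStage = lassoCoefs)))
}
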