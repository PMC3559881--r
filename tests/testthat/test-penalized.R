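test_that("orthonormal designs reduce to soft thresholding", {
    set.seed(42)
    n <- 64; p <- 8
    X0 <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
    Q <- qr.Q(qr(X0)) * sqrt(n)          # centered, Q'Q = n I
    y <- rnorm(n)
    bOls <- as.vector(crossprod(Q, y - mean(y))) / n
    for (lam in c(0.02, 0.08, 0.2)) {
        path <- lassoPath(Q, y, lambdas = c(0.5, lam),
                          standardize = FALSE, thresh = 1e-12)
        oracle <- sign(bOls) * pmax(abs(bOls) - lam, 0)
        expect_equal(unname(coefAt(path, lam)$beta), oracle,
                     tolerance = 1e-6)
    }
})

test_that("the unpenalized limit is OLS and the KKT bound kills all
           coefficients", {
    set.seed(11)
    X <- matrix(rnorm(60), 20, 3)
    y <- rnorm(20)
    path <- lassoPath(X, y, lambdas = c(1, 0), thresh = 1e-14)
    expect_equal(unname(coefAt(path, 0)$beta),
                 unname(coef(lm(y ~ X))[-1]), tolerance = 1e-6)
    lmax <- spliceSRE:::lambdaMaxKkt(methods::as(X, "CsparseMatrix"), y,
                                     standardize = TRUE)
    pm <- lassoPath(X, y, lambdas = c(2 * lmax, lmax * (1 + 1e-8)))
    expect_true(all(pm@beta == 0))
    # just below the bound at least one coefficient is active
    pb <- lassoPath(X, y, lambdas = c(lmax, lmax * 0.9))
    expect_gt(sum(coefAt(pb, lmax * 0.9)$beta != 0), 0)
    expect_error(lassoPath(X, c(y[-1], NA)), "finite")
})

test_that("the returned solution beats the all-zero vector at every
           lambda", {
    set.seed(8)
    X <- matrix(rnorm(200 * 10), 200, 10)
    y <- X[, 1] - 2 * X[, 2] + rnorm(200)
    path <- lassoPath(X, y, standardize = FALSE)
    n <- length(y)
    obj <- function(a0, b, lam)
        sum((y - a0 - X %*% b)^2) / (2 * n) + lam * sum(abs(b))
    zeroObj <- vapply(path@lambda, function(l) obj(mean(y),
                                                   rep(0, 10), l),
                      numeric(1))
    fitObj <- vapply(seq_along(path@lambda), function(k)
        obj(path@a0[k], as.vector(path@beta[, k]), path@lambda[k]),
        numeric(1))
    expect_true(all(fitObj <= zeroObj + 1e-10))
})

test_that("internal standardization reports back on the original scale", {
    set.seed(19)
    n <- 100
    X <- cbind(rnorm(n, sd = 5), rnorm(n, sd = 0.2), rbinom(n, 1, 0.3))
    y <- 0.3 * X[, 1] + 2 * X[, 2] + rnorm(n)
    # standardize by hand (1/n variance, as the solver does), fit raw,
    # map back: predictions must agree with the standardized fit
    sdn <- sqrt(colMeans(scale(X, scale = FALSE)^2))
    Xs <- sweep(X, 2, sdn, "/")
    lams <- exp(seq(log(0.5), log(0.001), length.out = 20))
    p1 <- lassoPath(X, y, lambdas = lams, standardize = TRUE,
                    thresh = 1e-12)
    p2 <- lassoPath(Xs, y, lambdas = lams, standardize = FALSE,
                    thresh = 1e-12)
    for (k in c(1, 10, 20)) {
        pred1 <- p1@a0[k] + X %*% as.vector(p1@beta[, k])
        pred2 <- p2@a0[k] + Xs %*% as.vector(p2@beta[, k])
        expect_equal(as.vector(pred1), as.vector(pred2),
                     tolerance = 1e-6)
    }
})

test_that("cross-validation is deterministic and recovers strong
           supports", {
    set.seed(30)
    n <- 200; p <- 40
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("v", seq_len(p))
    y <- as.vector(X[, 1:3] %*% c(3, -3, 3))   # noiseless
    cv1 <- cvSelectLambda(X, y, folds = 10, seed = 4)
    cv2 <- cvSelectLambda(X, y, folds = 10, seed = 4)
    expect_identical(cv1$lambdaMin, cv2$lambdaMin)
    expect_identical(cv1$betaMin, cv2$betaMin)
    expect_true(all(c("v1", "v2", "v3") %in%
                    names(which(cv1$betaMin != 0))))
    # pure-noise response: the chosen model stays small and the CV error
    # tracks Var(y)
    set.seed(31)
    yN <- rnorm(n)
    cvN <- cvSelectLambda(X, yN, folds = 10, seed = 4)
    expect_lte(sum(cvN$betaMin != 0), 15)
    expect_equal(min(cvN$cvm), var(yN), tolerance = 0.25)
})

test_that("fold counts above n fall back to leave-one-out", {
    set.seed(3)
    X <- matrix(rnorm(30 * 5), 30, 5)
    y <- rnorm(30)
    expect_warning(cv <- cvSelectLambda(X, y, folds = 100, seed = 1),
                   "falling back")
    expect_equal(cv$folds, 30)
})

test_that("adaptive Lasso with unit weights is the plain Lasso and
           zero-weight variables never re-enter", {
    set.seed(23)
    X <- matrix(rnorm(100 * 6), 100, 6)
    colnames(X) <- paste0("v", 1:6)
    y <- X[, 1] + rnorm(100)
    unit <- setNames(rep(1, 6), colnames(X))
    pa <- adaptiveLassoPath(X, y, unit)
    pl <- lassoPath(X, y, lambdas = pa@lambda, standardize = FALSE)
    expect_equal(unname(as.matrix(pa@beta)), unname(as.matrix(pl@beta)),
                 tolerance = 1e-10)
    # first-stage zeros are excluded over the whole path
    first <- setNames(c(1.2, 0, 0.4, 0, 0, 0), colnames(X))
    pz <- adaptiveLassoPath(X, y, first)
    expect_true(all(pz@beta[c("v2", "v4", "v5", "v6"), ] == 0))
    expect_warning(pe <- adaptiveLassoPath(X, y, setNames(rep(0, 6),
                                                          colnames(X))),
                   "empty")
    expect_true(all(pe@beta == 0))
})

test_that("adaptive Lasso gives fewer false positives than the Lasso", {
    nFp <- function(beta) sum(beta[-(1:5)] != 0)
    set.seed(71)
    fpL <- fpA <- numeric(20)
    for (s in seq_len(20)) {
        n <- 300; p <- 100
        X <- matrix(rnorm(n * p), n, p)
        colnames(X) <- paste0("v", seq_len(p))
        y <- as.vector(X[, 1:5] %*% rep(1, 5)) + rnorm(n)
        cvL <- cvSelectLambda(X, y, folds = 5, seed = s)
        fpL[s] <- nFp(cvL$betaMin)
        ad <- adaptiveLassoPath(X, y, cvL$betaMin)
        cvA <- cvSelectLambda(X, y, folds = 5, seed = s,
                              lambdas = ad@lambda, standardize = FALSE,
                              penaltyScale = 1 /
                                  pmax(abs(cvL$betaMin), 1e-12))
        fpA[s] <- nFp(coefAt(ad, cvA$lambdaMin)$beta)
    }
    expect_lt(mean(fpA), mean(fpL))
})
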