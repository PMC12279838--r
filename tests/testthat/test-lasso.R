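test_that("the lambda path follows the closed-form construction", {
    # orthonormal single predictor equal to the response: lambda_max = 1
    x <- matrix(c(1, -1, 1, -1), 4)
    y <- c(1, -1, 1, -1)
    lam <- lambdaPath(x, y, nlambda = 3)
    expect_equal(lam, c(1, 0.1, 0.01))
    expect_identical(length(lambdaPath(x, y, nlambda = 100)), 100L)
    expect_true(all(diff(lambdaPath(x, y, nlambda = 100)) < 0))
    expect_error(lambdaPath(x, rep(0, 4)), "degenerate response")
})

test_that("coefficients vanish at lambda_max and follow soft-thresholding on orthonormal designs", {
    withr::with_seed(31, {
        n <- 40
        # orthonormal-in-expectation design: exact orthonormalization below
        Z <- matrix(rnorm(n * 3), n, 3)
    })
    Q <- qr.Q(qr(scale(Z, scale = FALSE)))           # orthogonal columns
    Xo <- Q * sqrt(n)                                 # population sd 1, X'X/n = I
    b <- c(0.8, -0.4, 0)
    y <- as.numeric(Xo %*% b)
    fit <- fitLassoPath(Xo, y, nlambda = 25)
    # null model at the first (largest) lambda
    expect_identical(sum(fit$beta[, 1] != 0), 0L)
    expect_equal(fit$intercept[1], mean(y))
    # orthonormal solution: beta_j(lambda) = soft(beta_ols_j, lambda)
    bols <- as.numeric(crossprod(Xo, y) / n)
    for (k in c(5, 12, 25)) {
        lam <- fit$lambda[k]
        expected <- sign(bols) * pmax(abs(bols) - lam, 0)
        expect_equal(as.numeric(fit$beta[, k]), expected, tolerance = 1e-5)
    }
})

test_that("the coordinate descent solves the convex problem (proximal-gradient oracle)", {
    objDiff <- numeric()
    for (s in 1:10) {
        withr::with_seed(100 + s, {
            n <- sample(10:30, 1)
            p <- sample(5:50, 1)
            X <- matrix(rnorm(n * p), n, p)
            beta0 <- rnorm(p) * rbinom(p, 1, 0.3)
            y <- as.numeric(X %*% beta0 + rnorm(n))
        })
        fit <- fitLassoPath(X, y, nlambda = 20)
        std <- standardizeCols(X)
        yc <- y - mean(y)
        for (k in c(7, 20)) {
            lam <- fit$lambda[k]
            bstd <- as.numeric(fit$beta[, k]) * std$sd
            oracle <- fistaLasso(std$Xs, yc, lam)
            objDiff <- c(objDiff,
                         lassoObjectiveStd(std$Xs, yc, bstd, lam) -
                         lassoObjectiveStd(std$Xs, yc, oracle, lam))
        }
    }
    # our objective never worse than the oracle's beyond 1e-6 in either direction
    expect_lt(max(abs(objDiff)), 1e-6)
})

test_that("glmnet reaches the same objective on shared lambda sequences", {
    skip_if_not_installed("glmnet")
    for (s in 1:3) {
        withr::with_seed(200 + s, {
            n <- 25; p <- 40
            X <- matrix(rnorm(n * p), n, p)
            y <- as.numeric(X[, 1] - 0.5 * X[, 2] + rnorm(n))
        })
        fit <- fitLassoPath(X, y, nlambda = 30)
        gl <- glmnet::glmnet(X, y, lambda = fit$lambda, standardize = TRUE,
                             intercept = TRUE, thresh = 1e-14, maxit = 1e7)
        std <- standardizeCols(X)
        for (k in c(10, 30)) {
            lam <- fit$lambda[k]
            oursObj <- lassoObjectiveOrig(X, y, fit$intercept[k],
                                          as.numeric(fit$beta[, k]), lam, std$sd)
            glObj <- lassoObjectiveOrig(X, y, gl$a0[k],
                                        as.numeric(gl$beta[, k]), lam, std$sd)
            expect_lt(abs(oursObj - glObj), 1e-6)
        }
    }
})

test_that("KKT conditions hold at every path point", {
    withr::with_seed(77, {
        n <- 20; p <- 10
        X <- matrix(rnorm(n * p), n, p)
        y <- as.numeric(X %*% c(1, -1, rep(0, 8)) + rnorm(n, sd = 0.5))
    })
    fit <- fitLassoPath(X, y, nlambda = 30)
    std <- standardizeCols(X)
    yc <- y - mean(y)
    for (k in seq_along(fit$lambda)) {
        lam <- fit$lambda[k]
        bstd <- as.numeric(fit$beta[, k]) * std$sd
        grad <- as.numeric(crossprod(std$Xs, yc - std$Xs %*% bstd)) / n
        active <- bstd != 0
        expect_true(all(abs(grad[!active]) <= lam + 1e-6))
        if (any(active))
            expect_true(all(abs(abs(grad[active]) - lam) <= 1e-6))
    }
    # training MSE is non-increasing as lambda decreases
    mse <- vapply(seq_along(fit$lambda), function(k)
        mean((y - fit$intercept[k] - X %*% fit$beta[, k])^2), numeric(1))
    expect_true(all(diff(mse) <= 1e-10))
})

test_that("per-miRNA fitting keys paths by miRNA and records degenerate responses", {
    X <- randomExpr(30, 12, seed = 50, scaleTag = "compressed")
    vals <- withr::with_seed(51, matrix(runif(5 * 12), 5, 12))
    vals[3, ] <- 0.5  # constant miRNA
    Y <- makeExpr(vals, scaleTag = "compressed",
                  features = sprintf("mir%d", 1:5))
    ms <- suppressMessages(fitLassoPerMirna(X, Y, nlambda = 15))
    expect_identical(names(ms@paths), sprintf("mir%d", 1:5))
    expect_true(isTRUE(ms@paths$mir3$skipped))
    expect_identical(sum(vapply(ms@paths, function(p) isTRUE(p$skipped),
                                logical(1))), 1L)

    # skipped miRNAs are predicted at their training mean
    pred <- predictExpression(ms, X, lambdaChoice = "minimal")
    expect_equal(unname(exprValues(pred)["mir3", ]),
                 rep(0.5, 12), tolerance = 1e-12)

    # tenth-largest lambda requires a long-enough path
    short <- suppressMessages(fitLassoPerMirna(X, Y, nlambda = 5))
    expect_error(predictExpression(short, X, lambdaChoice = "tenth_largest"),
                 "10th")
})

test_that("minimal-lambda training error is below the tenth-largest one", {
    sim <- simulatePairedDataset(simConfig(nMirna = 20, nMrna = 100,
                                           seed = 60))
    Xc <- applyCompression(sim$mrna, fitCompression(sim$mrna))
    Yc <- applyCompression(sim$mirna, fitCompression(sim$mirna))
    ms <- fitLassoPerMirna(Xc, Yc)
    pMin <- exprValues(predictExpression(ms, Xc, "minimal"))
    p10 <- exprValues(predictExpression(ms, Xc, "tenth_largest"))
    truth <- exprValues(Yc)
    expect_lt(mean((pMin - truth)^2), mean((p10 - truth)^2))

    # within-data recovery at the minimal lambda
    r <- samplewiseCorrelation(Yc, predictExpression(ms, Xc, "minimal"))
    expect_gte(median(r), 0.9)
})
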