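tinyCfg <- function(...) {
    args <- list(hiddenSizes = c(8L, 4L), maxEpochs = 25L, batchSize = 8L,
                 seed = 1L)
    args[names(list(...))] <- list(...)
    do.call(mlpConfig, args)
}

test_that("the architecture builder reflects configured widths", {
    a <- buildMLP(14977, 499)
    expect_identical(a$widths, c(1024L, 512L, 256L, 128L))
    expect_identical(a$nIn, 14977L)
    expect_identical(a$nOut, 499L)
    dense <- a$layers[a$layers$type == "dense", ]
    expect_identical(dense$width, c(1024L, 512L, 256L, 128L))

    expect_identical(buildMLP(1, 1)$nIn, 1L)
    b <- buildMLP(30, 2, mlpConfig(hiddenSizes = 8L))
    expect_identical(b$widths, 8L)
    expect_false("batchnorm" %in%
        buildMLP(3, 2, mlpConfig(hiddenSizes = 4L,
                                 batchnormAfterDense = FALSE))$layers$type)
})

test_that("analytic gradients match finite differences", {
    for (useBn in c(FALSE, TRUE)) {
        params <- withr::with_seed(42,
            crossmir:::.cpp_mlp_init(7L, c(5L, 4L), 3L, useBn))
        X <- withr::with_seed(1, matrix(rnorm(6 * 7), 6, 7))
        Y <- withr::with_seed(2, matrix(rnorm(6 * 3), 6, 3))
        l2 <- 1e-3; eps <- 1e-3
        ana <- crossmir:::.cpp_mlp_loss_grad(params, X, Y, l2, eps)
        lossAt <- function(p) crossmir:::.cpp_mlp_loss_grad(p, X, Y, l2, eps)$loss
        h <- 1e-5
        numDiff <- function(field, l, i, j) {
            pp <- params; pm <- params
            pp[[field]][[l]][i, j] <- pp[[field]][[l]][i, j] + h
            pm[[field]][[l]][i, j] <- pm[[field]][[l]][i, j] - h
            (lossAt(pp) - lossAt(pm)) / (2 * h)
        }
        anaV <- numV <- numeric()
        for (l in 1:3) {
            W <- params$W[[l]]
            for (ij in list(c(1, 1), c(nrow(W), ncol(W)), c(1, ncol(W)))) {
                anaV <- c(anaV, ana$gW[[l]][ij[1], ij[2]])
                numV <- c(numV, numDiff("W", l, ij[1], ij[2]))
            }
            anaV <- c(anaV, as.numeric(ana$gb[[l]])[1])
            numV <- c(numV, numDiff("b", l, 1, 1))
        }
        if (useBn) {
            anaV <- c(anaV, as.numeric(ana$ggamma[[1]])[2],
                      as.numeric(ana$gbeta[[1]])[3])
            numV <- c(numV, numDiff("gamma", 1, 1, 2),
                      numDiff("beta", 1, 1, 3))
        }
        expect_lt(max(abs(anaV - numV) / pmax(abs(numV), 1e-3)), 1e-4)
    }
})

test_that("training a noiseless linear map reduces the loss within the epoch budget", {
    n <- 100; p <- 20; q <- 5
    W <- withr::with_seed(3, matrix(rnorm(p * q, sd = 0.3), p, q))
    Xm <- withr::with_seed(4, matrix(runif(n * p), n, p))
    X <- makeExpr(t(Xm), scaleTag = "compressed",
                  features = sprintf("g%d", 1:p), samples = sprintf("s%d", 1:n))
    Y <- makeExpr(t(Xm %*% W), scaleTag = "compressed",
                  features = sprintf("m%d", 1:q), samples = sprintf("s%d", 1:n))
    fit <- trainMLP(X, Y, tinyCfg())
    h <- fit@history
    expect_lte(nrow(h), 25L)
    expect_identical(names(h),
                     c("epoch", "train_loss", "val_loss", "learning_rate"))
    expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
    expect_true(all(diff(h$learning_rate) <= 0))
})

test_that("training is deterministic under a fixed seed", {
    X <- randomExpr(15, 24, seed = 5, scaleTag = "compressed")
    Y <- randomExpr(6, 24, seed = 6, scaleTag = "compressed")
    f1 <- trainMLP(X, Y, tinyCfg())
    f2 <- trainMLP(X, Y, tinyCfg())
    expect_equal(f1@history$train_loss[nrow(f1@history)],
                 f2@history$train_loss[nrow(f2@history)], tolerance = 1e-8)
    expect_identical(f1@weights[[1]]$W, f2@weights[[1]]$W)
    f3 <- trainMLP(X, Y, tinyCfg(seed = 2L))
    expect_false(identical(f1@weights[[1]]$W, f3@weights[[1]]$W))
})

test_that("prediction is deterministic, sample-equivariant and shape-checked", {
    X <- randomExpr(15, 24, seed = 7, scaleTag = "compressed")
    Y <- randomExpr(6, 24, seed = 8, scaleTag = "compressed")
    fit <- trainMLP(X, Y, tinyCfg())
    p1 <- predictExpression(fit, X)
    p2 <- predictExpression(fit, X)
    expect_identical(exprValues(p1), exprValues(p2))
    expect_identical(dim(exprValues(p1)), c(6L, 24L))

    # permuting input samples permutes predictions identically
    perm <- withr::with_seed(9, sample(sampleIds(X)))
    Xp <- makeExpr(exprValues(X)[, perm], scaleTag = "compressed",
                   features = featureIds(X), samples = perm)
    pp <- predictExpression(fit, Xp)
    expect_identical(exprValues(pp), exprValues(p1)[, perm])

    # single sample in, single column out
    X1 <- makeExpr(exprValues(X)[, 1, drop = FALSE], scaleTag = "compressed",
                   features = featureIds(X), samples = sampleIds(X)[1])
    expect_identical(dim(exprValues(predictExpression(fit, X1))), c(6L, 1L))

    # feature mismatch rejected
    Xbad <- makeExpr(exprValues(X), scaleTag = "compressed",
                     features = rev(featureIds(X)))
    expect_error(predictExpression(fit, Xbad), "feature IDs")
})

test_that("too few samples for the validation split advise augmentation", {
    X <- randomExpr(5, 4, seed = 10, scaleTag = "compressed")
    Y <- randomExpr(2, 4, seed = 11, scaleTag = "compressed")
    expect_error(trainMLP(X, Y, tinyCfg()), "augment")
})

test_that("model checkpoints round-trip through save/load", {
    X <- randomExpr(10, 20, seed = 12, scaleTag = "compressed")
    Y <- randomExpr(3, 20, seed = 13, scaleTag = "compressed")
    fit <- trainMLP(X, Y, tinyCfg(maxEpochs = 5L))
    path <- tempfile(fileext = ".rds")
    saveMLPModel(fit, path)
    expect_true(file.exists(paste0(path, ".json")))
    back <- loadMLPModel(path)
    expect_identical(exprValues(predictExpression(back, X)),
                     exprValues(predictExpression(fit, X)))
})
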