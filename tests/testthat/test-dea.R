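test_that("null features give zero logFC and p-value one", {
    v <- matrix(c(1, 2, 3, 4, 1, 2, 3, 4), 1)  # identical group profiles
    X <- makeExpr(rbind(v, withr::with_seed(1, matrix(rnorm(8 * 19), 19, 8))))
    g <- twoGroups(4, 4)
    res <- moderatedTTest(X, g)
    tab <- deaTable(res)
    expect_equal(tab$logFC[1], 0)
    expect_equal(tab$t[1], 0)
    expect_equal(tab$P.Value[1], 1)
    expect_true(all(tab$P.Value > 0 & tab$P.Value <= 1))
    # p monotone decreasing in |t|
    o <- order(abs(tab$t))
    expect_true(all(diff(tab$P.Value[o]) <= 1e-12))
})

test_that("hyperparameters and p-values match an independent moment-estimator oracle", {
    withr::with_seed(7, {
        sds <- sqrt(rchisq(20, df = 3) / 3)
        v <- matrix(rnorm(20 * 8, sd = rep(sds, 8)), 20, 8)
        v[1:5, 5:8] <- v[1:5, 5:8] + 1
    })
    X <- makeExpr(v)
    g <- twoGroups(4, 4)
    res <- moderatedTTest(X, g)
    orc <- deaOracle(v, rep(c(FALSE, TRUE), each = 4))
    expect_true(is.finite(res@d0))
    expect_equal(res@d0, orc$d0, tolerance = 1e-6)
    expect_equal(res@s0sq, orc$s0sq, tolerance = 1e-6)
    expect_equal(deaTable(res)$logFC, orc$logfc, tolerance = 1e-12)
    expect_equal(deaTable(res)$t, orc$t, tolerance = 1e-6)
    expect_equal(deaTable(res)$P.Value, orc$p, tolerance = 1e-6)
})

test_that("results agree with limma's moderated t on a two-group design", {
    skip_if_not_installed("limma")
    withr::with_seed(8, {
        sds <- sqrt(rchisq(50, df = 4) / 4)
        v <- matrix(rnorm(50 * 10, sd = rep(sds, 10)), 50, 10)
        v[1:10, 6:10] <- v[1:10, 6:10] + 0.8
    })
    X <- makeExpr(v)
    res <- moderatedTTest(X, twoGroups(5, 5))
    design <- cbind(1, rep(0:1, each = 5))
    ebf <- limma::eBayes(limma::lmFit(v, design))
    expect_equal(res@d0, ebf$df.prior, tolerance = 1e-4)
    expect_equal(res@s0sq, ebf$s2.prior, tolerance = 1e-4)
    expect_equal(deaTable(res)$logFC, unname(ebf$coefficients[, 2]),
                 tolerance = 1e-10)
    expect_equal(deaTable(res)$t, unname(ebf$t[, 2]), tolerance = 1e-6)
    expect_equal(deaTable(res)$P.Value, unname(ebf$p.value[, 2]),
                 tolerance = 1e-6)
})

test_that("forcing d0 = 0 recovers the ordinary pooled two-sample t", {
    v <- withr::with_seed(9, matrix(rnorm(30 * 9, mean = 5), 30, 9))
    X <- makeExpr(v)
    res <- moderatedTTest(X, twoGroups(4, 5), d0Override = 0)
    tab <- deaTable(res)
    for (gi in c(1, 15, 30)) {
        a <- v[gi, 1:4]; b <- v[gi, 5:9]
        sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 7
        tcl <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / 4 + 1 / 5))
        expect_equal(tab$t[gi], tcl, tolerance = 1e-9)
        expect_equal(tab$P.Value[gi], 2 * pt(-abs(tcl), 7), tolerance = 1e-9)
    }
})

test_that("equal-variance data fall in the infinite-prior-df branch", {
    pattern <- withr::with_seed(10, rnorm(8))
    sign <- rep(c(1, -1), 20)
    # every feature carries the same within-group scatter (var(e) = 0),
    # so the prior degrees of freedom are infinite
    v <- outer(sign, pattern) + seq_len(40)
    X <- makeExpr(v)
    res <- moderatedTTest(X, twoGroups(4, 4))
    expect_true(is.infinite(res@d0))
    # posterior variances all collapse to s0^2: t = logFC/(s0*sqrt(2/4))
    tab <- deaTable(res)
    expect_equal(tab$t, tab$logFC / (sqrt(res@s0sq) * sqrt(0.5)),
                 tolerance = 1e-12)
})

test_that("logFC is shift-invariant and scales linearly with the data", {
    Y <- randomExpr(25, 10, seed = 11, scaleTag = "compressed")
    g <- twoGroups(5, 5)
    r1 <- moderatedTTest(Y, g)
    shifted <- makeExpr(exprValues(Y) + 3, scaleTag = "compressed",
                        features = featureIds(Y), samples = sampleIds(Y))
    r2 <- moderatedTTest(shifted, g)
    expect_equal(deaTable(r2)$logFC, deaTable(r1)$logFC, tolerance = 1e-12)

    # affine predicted data: logfc_pred = a * logfc_true
    a <- 0.6; b <- 0.2
    pred <- makeExpr(a * exprValues(Y) + b, scaleTag = "compressed",
                     features = featureIds(Y), samples = sampleIds(Y))
    pair <- runDEAPair(Y, pred, g)
    expect_equal(deaTable(pair$pred)$logFC, a * deaTable(pair$true)$logFC,
                 tolerance = 1e-12)
    # identical inputs give identical results
    pair2 <- runDEAPair(Y, Y, g)
    expect_identical(deaTable(pair2$true), deaTable(pair2$pred))
})

test_that("null data produce approximately uniform p-values", {
    v <- withr::with_seed(12, matrix(rnorm(1000 * 10), 1000, 10))
    res <- moderatedTTest(makeExpr(v), twoGroups(5, 5))
    ks <- suppressWarnings(stats::ks.test(deaTable(res)$P.Value, "punif"))
    expect_gt(ks$p.value, 0.01)
})
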