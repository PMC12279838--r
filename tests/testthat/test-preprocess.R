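test_that("quantile normalization reproduces the hand-worked example and is idempotent", {
    X <- makeExpr(matrix(c(5, 2, 3, 4, 1, 8), 3, 2))
    Q <- quantileNormalize(X)
    expect_equal(unname(exprValues(Q)),
                 matrix(c(6.5, 1.5, 3.5, 3.5, 1.5, 6.5), 3, 2))

    # identical columns are left unchanged
    same <- makeExpr(matrix(c(3, 1, 2, 3, 1, 2), 3, 2))
    expect_equal(exprValues(quantileNormalize(same)), exprValues(same))

    # idempotence on a random matrix
    R <- randomExpr(40, 6, seed = 2)
    Q1 <- quantileNormalize(R)
    Q2 <- quantileNormalize(Q1)
    expect_lt(max(abs(exprValues(Q2) - exprValues(Q1))), 1e-9)

    expect_error(quantileNormalize(makeExpr(matrix(1:3, 3, 1))), ">=2 samples")
})

test_that("quantile normalization gives ties the mean of the spanned reference quantiles", {
    # column 1 has a two-way tie at value 2 occupying rank positions 2 and 3
    X <- makeExpr(matrix(c(1, 2, 2, 7,
                           0, 4, 6, 10), 4, 2))
    ref <- rowMeans(apply(exprValues(X), 2, sort))
    Q <- exprValues(quantileNormalize(X))
    expect_equal(unname(Q[2, 1]), mean(ref[2:3]))
    expect_equal(unname(Q[3, 1]), mean(ref[2:3]))
    expect_equal(unname(Q[c(1, 4), 1]), unname(ref[c(1, 4)]))
    expect_equal(unname(Q[, 2]), unname(ref))
})

test_that("quantile normalization agrees with limma on tie-free data", {
    skip_if_not_installed("limma")
    R <- randomExpr(30, 5, seed = 9)
    ours <- exprValues(quantileNormalize(R))
    theirs <- limma::normalizeQuantiles(exprValues(R))
    expect_equal(unname(ours), unname(theirs), tolerance = 1e-12)
})

test_that("log-CPM transform matches its closed form and limma's voom", {
    # count 0 in a library of size 999999: log2(0.5/(1e6) * 1e6) = -1
    cts <- makeExpr(matrix(c(0, 999999), 2, 1), scaleTag = "counts")
    lc <- exprValues(voomLogCPM(cts))
    expect_equal(unname(lc[1, 1]), -1)
    # single feature carrying the whole library
    one <- makeExpr(matrix(c(1e6), 1, 1), scaleTag = "counts")
    expect_equal(unname(exprValues(voomLogCPM(one))[1, 1]),
                 log2((1e6 + 0.5) / (1e6 + 1) * 1e6), tolerance = 1e-12)
    expect_lt(abs(unname(exprValues(voomLogCPM(one))[1, 1]) - log2(1e6)), 0.01)

    # doubling all counts leaves log-CPM nearly unchanged for large counts
    big <- withr::with_seed(4, matrix(rpois(200, 5000), 20, 10))
    l1 <- exprValues(voomLogCPM(makeExpr(big, scaleTag = "counts")))
    l2 <- exprValues(voomLogCPM(makeExpr(2 * big, scaleTag = "counts")))
    expect_lt(max(abs(l1 - l2)), 0.01)

    # strictly monotone in the count at fixed library size
    expect_true(all(diff(exprValues(voomLogCPM(makeExpr(
        matrix(c(0, 1, 5, 100, 894), 5, 1), scaleTag = "counts")))[, 1]) > 0))

    expect_error(voomLogCPM(makeExpr(matrix(-1, 1, 1), scaleTag = "counts")),
                 "non-negative")
    expect_error(voomLogCPM(randomExpr(2, 2, seed = 1)), "counts")

    skip_if_not_installed("limma")
    v <- suppressWarnings(limma::voom(big))
    expect_equal(unname(l1), unname(v$E), tolerance = 1e-10)
})

test_that("compression maps extremes to 0/1 and clips foreign-scale values", {
    X <- makeExpr(matrix(c(1, 3, 5), 3, 1))
    p <- fitCompression(X)
    expect_equal(c(p@globalMin, p@globalMax), c(1, 5))
    C <- applyCompression(X, p)
    expect_equal(unname(exprValues(C)[, 1]), c(0, 0.5, 1))
    expect_identical(scaleTag(C), "compressed")

    # own params always attain 0 and 1 exactly
    R <- randomExpr(25, 4, seed = 5)
    CR <- applyCompression(R, fitCompression(R))
    expect_identical(min(exprValues(CR)), 0)
    expect_identical(max(exprValues(CR)), 1)

    # foreign params clip with a count
    Y <- makeExpr(matrix(c(2, 7), 2, 1))
    expect_message(CY <- applyCompression(Y, p), "1 value")
    expect_equal(unname(exprValues(CY)[, 1]), c(0.25, 1))
    expect_identical(attr(exprValues(CY), "clipped"), 1L)

    expect_error(fitCompression(makeExpr(matrix(2, 2, 2))), "constant")
})

test_that("low-expression filter removes floor(fraction*n) features, ties by input order", {
    X <- randomExpr(10, 4, seed = 6)
    expect_identical(nrow(exprValues(filterLowExpressed(X, 0.2))), 8L)
    expect_identical(exprValues(filterLowExpressed(X, 0)), exprValues(X))

    # construct a tie at the cut: features f1 and f2 share the lowest mean
    m <- matrix(c(1, 1, 3, 4,
                  1, 1, 3, 4), nrow = 4)
    tied <- makeExpr(m)  # f1 and f2 both have mean 1
    kept <- filterLowExpressed(tied, 0.25)  # drop exactly one
    expect_identical(featureIds(kept), c("f2", "f3", "f4"))

    # survivor count invariant over random fractions
    for (fr in c(0.1, 0.33, 0.5, 0.9)) {
        n <- 13L
        Xf <- randomExpr(n, 3, seed = 7)
        expect_identical(nrow(exprValues(filterLowExpressed(Xf, fr))),
                         n - as.integer(floor(fr * n)))
    }
    expect_error(filterLowExpressed(randomExpr(3, 2, seed = 8), 1), "fraction")
})
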