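test_that("simulated datasets satisfy the container invariants and are seed-reproducible", {
    cfg <- simConfig(nMirna = 40, nMrna = 200, seed = 1)
    sim <- simulatePairedDataset(cfg)
    expect_s4_class(sim$mrna, "ExpressionMatrix")
    expect_identical(dim(exprValues(sim$mrna)), c(200L, 10L))
    expect_identical(dim(exprValues(sim$mirna)), c(40L, 10L))
    expect_identical(sampleIds(sim$mrna), sampleIds(sim$mirna))
    expect_identical(scaleTag(sim$mrna), "log_intensity")
    expect_true(all(lengths(sim$truth@targetMap) == cfg$targetsPerMirna))
    expect_identical(length(sim$truth@deMirnaIds),
                     as.integer(round(0.2 * 40)))

    sim2 <- simulatePairedDataset(cfg)
    expect_identical(exprValues(sim2$mrna), exprValues(sim$mrna))
    expect_identical(exprValues(sim2$mirna), exprValues(sim$mirna))
    sim3 <- simulatePairedDataset(simConfig(nMirna = 40, nMrna = 200, seed = 2))
    expect_false(identical(exprValues(sim3$mirna), exprValues(sim$mirna)))

    # reusing a truth keeps the structure but redraws samples
    sim4 <- simulatePairedDataset(simConfig(nMirna = 40, nMrna = 200, seed = 5),
                                  truth = sim$truth)
    expect_identical(sim4$truth@deMirnaIds, sim$truth@deMirnaIds)
    expect_false(identical(exprValues(sim4$mirna), exprValues(sim$mirna)))
})

test_that("the fold-change oracle matches the construction and the empirical data", {
    cfg <- simConfig(seed = 3)
    sim <- simulatePairedDataset(cfg)
    lfc <- expectedMirnaLogFC(sim$truth)
    expect_true(all(lfc[setdiff(names(lfc), sim$truth@deMirnaIds)] == 0))
    expect_true(all(abs(lfc[sim$truth@deMirnaIds]) == cfg$deEffect))

    cond <- conditions(sim$groups)
    v <- exprValues(sim$mirna)
    emp <- rowMeans(v[, cond == "diseased"]) - rowMeans(v[, cond == "control"])
    expect_gte(pearsonR(emp, unname(lfc)), 0.9)
})

test_that("DE miRNAs repress their targets in the constructed direction", {
    cfg <- simConfig(seed = 4)
    sim <- simulatePairedDataset(cfg)
    cond <- conditions(sim$groups)
    vm <- exprValues(sim$mrna)
    empM <- rowMeans(vm[, cond == "diseased"]) - rowMeans(vm[, cond == "control"])
    ok <- vapply(sim$truth@deMirnaIds, function(id) {
        tg <- sim$truth@targetMap[[id]]
        sgn <- sim$truth@deSign[[id]]
        # positive DE shift pushes target mRNAs down, and vice versa
        sign(mean(empM[tg])) == -sgn
    }, logical(1))
    expect_gte(mean(ok), 0.9)
})

test_that("stronger effects give larger empirical miRNA fold changes", {
    meanAbs <- vapply(c(0.5, 1, 2), function(d) {
        sim <- simulatePairedDataset(simConfig(nMirna = 60, nMrna = 300,
                                               deEffect = d, seed = 11))
        cond <- conditions(sim$groups)
        v <- exprValues(sim$mirna)
        emp <- rowMeans(v[, cond == "diseased"]) -
            rowMeans(v[, cond == "control"])
        mean(abs(emp[sim$truth@deMirnaIds]))
    }, numeric(1))
    expect_true(all(diff(meanAbs) > 0))
})

test_that("a null simulation yields uniform DEA p-values", {
    sim <- simulatePairedDataset(simConfig(fracDeMirna = 0, nMirna = 1000,
                                           nMrna = 200, seed = 12))
    res <- moderatedTTest(sim$mirna, sim$groups)
    ks <- suppressWarnings(stats::ks.test(deaTable(res)$P.Value, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("simulated datasets round-trip through the standard file formats", {
    sim <- simulatePairedDataset(simConfig(nMirna = 8, nMrna = 30, seed = 13))
    dir <- tempfile()
    writeSimulatedDataset(sim, dir)
    back <- readExpressionMatrix(file.path(dir, "mirna.tsv"))
    expect_lt(max(abs(exprValues(back) - exprValues(sim$mirna))), 1e-9)
    g <- readSampleGroups(file.path(dir, "samples.tsv"))
    expect_identical(conditions(g), conditions(sim$groups))
})
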