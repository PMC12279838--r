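# small deterministic fixtures shared across test files

makeExpr <- function(values, scaleTag = "log_intensity",
                     features = sprintf("f%d", seq_len(nrow(values))),
                     samples = sprintf("s%d", seq_len(ncol(values)))) {
    dimnames(values) <- list(features, samples)
    ExpressionMatrix(values, scaleTag = scaleTag)
}

randomExpr <- function(nf, ns, seed, sd = 1, mean = 5,
                       scaleTag = "log_intensity") {
    withr::with_seed(seed,
        makeExpr(matrix(rnorm(nf * ns, mean, sd), nf, ns),
                 scaleTag = scaleTag))
}

twoGroups <- function(n1, n2) {
    ids <- c(sprintf("s%d", seq_len(n1)), sprintf("s%d", n1 + seq_len(n2)))
    SampleGroups(setNames(rep(c("control", "diseased"), c(n1, n2)), ids))
}

writeMatrixFile <- function(lines) {
    path <- tempfile(fileext = ".tsv")
    writeLines(lines, path)
    path
}
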