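#' Generate the LASSO penalty path
#'
#' Computes the decreasing lambda sequence used by the per-miRNA LASSO fits:
#' \code{lambda_max = max_j |<x_j, y>| / n} on the standardized predictors,
#' followed by \code{nlambda} log-equispaced values down to
#' \code{lambda_max * ratio}. At \code{lambda_max} every coefficient is
#' exactly zero.
#'
#' @param X numeric matrix, samples x predictors, columns standardized to
#'   mean 0 and standard deviation 1 (population, i.e. 1/n, normalization).
#' @param y centered response vector.
#' @param nlambda path length (default 100).
#' @param ratio smallest lambda as a fraction of \code{lambda_max}.
#' @return strictly decreasing numeric vector of length \code{nlambda}.
#' @examples
#' x <- matrix(c(1, -1, 1, -1), 4)
#' lambdaPath(x, c(1, -1, 1, -1), nlambda = 3)
#' @export
lambdaPath <- function(X, y, nlambda = 100L, ratio = 0.01) {
    stopifnot(nlambda >= 1, ratio > 0, ratio < 1)
    n <- length(y)
    lmax <- max(abs(crossprod(X, y))) / n
    if (lmax == 0)
        stop("degenerate response: lambda_max is 0 (constant or orthogonal y)")
    if (nlambda == 1L) return(lmax)
    exp(seq(log(lmax), log(lmax * ratio), length.out = nlambda))
}

# map standardized-scale coefficients back to the original predictor scale,
# re-inserting excluded constant predictors as zero rows
.origScaleBeta <- function(bstd, std, p) {
    bs <- Matrix::Diagonal(x = 1 / std$sd[std$ok]) %*% bstd
    if (all(std$ok)) return(methods::as(bs, "CsparseMatrix"))
    beta <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                 dims = c(p, ncol(bstd)))
    beta[std$ok, ] <- bs
    methods::as(beta, "CsparseMatrix")
}

# standardize columns to mean 0, population sd 1; constant columns flagged
.standardize <- function(X) {
    mu <- colMeans(X)
    Xc <- sweep(X, 2L, mu)
    sd0 <- sqrt(colMeans(Xc^2))
    ok <- sd0 > 0
    Xs <- sweep(Xc[, ok, drop = FALSE], 2L, sd0[ok], "/")
    list(Xs = Xs, mu = mu, sd = sd0, ok = ok)
}

#' Fit a LASSO regularization path for one response
#'
#' Minimizes \code{(1/2n) ||y - b0 - X beta||^2 + lambda ||beta||_1} on the
#' standardized predictor scale for every lambda of the automatically
#' generated path, by cyclic coordinate descent with soft-thresholding and
#' warm starts. Coefficients are returned on the original predictor scale.
#' Constant predictors are excluded (coefficient 0).
#'
#' @param X numeric matrix, samples x predictors (original scale; may have
#'   far more predictors than samples).
#' @param y response vector.
#' @param nlambda,ratio see \code{\link{lambdaPath}}.
#' @param tol convergence threshold on the largest coefficient change per
#'   cycle (standardized scale).
#' @return list of class \code{lassoPath}: \code{lambda}, sparse
#'   \code{beta} (predictors x nlambda, original scale), \code{intercept}
#'   per lambda, \code{trainMean} (mean of \code{y}), and the
#'   standardization \code{center}/\code{scale}.
#' @export
fitLassoPath <- function(X, y, nlambda = 100L, ratio = 0.01, tol = 1e-7) {
    X <- as.matrix(X)
    if (!all(is.finite(X)) || !all(is.finite(y)))
        stop("non-finite values in predictors or response")
    if (nrow(X) != length(y)) stop("X and y disagree on sample count")
    if (nrow(X) < 2L) stop("need at least 2 samples")
    std <- .standardize(X)
    yc <- y - mean(y)
    lam <- lambdaPath(std$Xs, yc, nlambda = nlambda, ratio = ratio)
    n <- length(y)
    G <- crossprod(std$Xs) / n
    c0 <- as.numeric(crossprod(std$Xs, yc)) / n
    bstd <- .cpp_lasso_path(G, c0, lam, tol, 100000L)
    p <- ncol(X)
    beta <- .origScaleBeta(bstd, std, p)
    intercept <- mean(y) - as.numeric(Matrix::crossprod(beta, std$mu))
    structure(list(lambda = lam, beta = beta, intercept = intercept,
                   trainMean = mean(y), center = std$mu, scale = std$sd),
              class = "lassoPath")
}

#' Fit one LASSO path per miRNA
#'
#' Trains an individual LASSO model for every miRNA, using the whole mRNA
#' matrix as predictors. The standardized Gram matrix is computed once and
#' shared across the per-miRNA coordinate-descent fits. miRNAs with a
#' constant (degenerate) response are recorded as skipped and later
#' predicted at their training mean.
#'
#' @param X \linkS4class{ExpressionMatrix} of compressed mRNA predictors.
#' @param Y \linkS4class{ExpressionMatrix} of compressed miRNA responses,
#'   same samples in the same order.
#' @param nlambda,ratio,tol see \code{\link{fitLassoPath}}.
#' @return A \linkS4class{LassoModelSet}.
#' @export
fitLassoPerMirna <- function(X, Y, nlambda = 100L, ratio = 0.01, tol = 1e-7) {
    if (!identical(sampleIds(X), sampleIds(Y)))
        stop("X and Y must share sample IDs in the same order")
    Xm <- t(exprValues(X))
    Ym <- t(exprValues(Y))
    n <- nrow(Xm)
    std <- .standardize(Xm)
    G <- crossprod(std$Xs) / n
    p <- ncol(Xm)
    paths <- lapply(seq_len(ncol(Ym)), function(g) {
        y <- Ym[, g]
        if (sd(y) == 0 || max(abs(crossprod(std$Xs, y - mean(y)))) == 0)
            return(list(skipped = TRUE, trainMean = mean(y)))
        yc <- y - mean(y)
        lam <- lambdaPath(std$Xs, yc, nlambda = nlambda, ratio = ratio)
        c0 <- as.numeric(crossprod(std$Xs, yc)) / n
        bstd <- .cpp_lasso_path(G, c0, lam, tol, 100000L)
        beta <- .origScaleBeta(bstd, std, p)
        list(lambda = lam, beta = beta,
             intercept = mean(y) - as.numeric(Matrix::crossprod(beta, std$mu)),
             trainMean = mean(y))
    })
    names(paths) <- featureIds(Y)
    nskip <- sum(vapply(paths, function(x) isTRUE(x$skipped), logical(1)))
    if (nskip > 0) message(nskip, " degenerate miRNA response(s) skipped")
    new("LassoModelSet", predictorIds = featureIds(X),
        responseIds = featureIds(Y), paths = paths,
        nlambda = as.integer(nlambda))
}

#' @describeIn predictExpression predicts each miRNA from its LASSO path at
#'   the chosen penalty: \code{"minimal"} uses the last (smallest) lambda of
#'   the path, \code{"tenth_largest"} the 10th entry of the decreasing
#'   sequence. Skipped miRNAs are predicted at their training mean.
#' @param lambdaChoice \code{"minimal"} or \code{"tenth_largest"}.
#' @export
setMethod("predictExpression", "LassoModelSet",
          function(object, X, lambdaChoice = c("minimal", "tenth_largest"), ...) {
    lambdaChoice <- match.arg(lambdaChoice)
    if (!identical(featureIds(X), object@predictorIds))
        stop("feature IDs of X do not match the model's predictors")
    idx <- if (lambdaChoice == "minimal") object@nlambda else 10L
    if (idx > object@nlambda)
        stop("path holds only ", object@nlambda,
             " lambdas; cannot take the 10th largest")
    Xm <- t(exprValues(X))
    ns <- nrow(Xm)
    out <- matrix(NA_real_, length(object@paths), ns,
                  dimnames = list(object@responseIds, sampleIds(X)))
    for (g in seq_along(object@paths)) {
        pth <- object@paths[[g]]
        if (isTRUE(pth$skipped)) {
            out[g, ] <- pth$trainMean
        } else {
            out[g, ] <- as.numeric(Xm %*% pth$beta[, idx]) + pth$intercept[idx]
        }
    }
    ExpressionMatrix(out, scaleTag = "compressed")
})

#' Serialize a LassoModelSet to tabular coefficients plus JSON metadata
#'
#' Writes the non-zero coefficients as a long-format gzipped TSV
#' (miRNA, predictor, lambda index, value) and the lambdas, intercepts and
#' feature IDs as JSON.
#'
#' @param models a \linkS4class{LassoModelSet}.
#' @param prefix output path prefix; writes \code{<prefix>.tsv.gz} and
#'   \code{<prefix>.json}.
#' @return \code{prefix}, invisibly.
#' @export
writeLassoModelSet <- function(models, prefix) {
    rows <- lapply(names(models@paths), function(id) {
        pth <- models@paths[[id]]
        if (isTRUE(pth$skipped)) return(NULL)
        sm <- Matrix::summary(pth$beta)
        if (nrow(sm) == 0) return(NULL)
        data.frame(mirna = id, predictor = models@predictorIds[sm$i],
                   lambda_index = sm$j, value = sm$x)
    })
    con <- gzfile(paste0(prefix, ".tsv.gz"), "w")
    write.table(do.call(rbind, rows), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
    meta <- list(predictor_ids = models@predictorIds,
                 response_ids = models@responseIds,
                 nlambda = models@nlambda,
                 lambdas = lapply(models@paths, function(p)
                     if (isTRUE(p$skipped)) "skipped" else p$lambda),
                 intercepts = lapply(models@paths, function(p)
                     if (isTRUE(p$skipped)) p$trainMean else p$intercept))
    jsonlite::write_json(meta, paste0(prefix, ".json"), digits = NA)
    invisible(prefix)
}
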