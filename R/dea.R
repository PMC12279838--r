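# solve trigamma(y) = x by monotone root-finding (trigamma is strictly
# decreasing on (0, Inf)); used for the prior degrees of freedom
.solveTrigamma <- function(x) {
    lo <- 1e-8; hi <- 1e8
    if (x >= trigamma(lo)) return(lo)
    if (x <= trigamma(hi)) return(hi)
    stats::uniroot(function(y) trigamma(y) - x, lower = lo, upper = hi,
                   tol = 1e-12, maxiter = 2000L)$root
}

#' Two-group moderated t-test with empirical-Bayes variance shrinkage
#'
#' For every feature computes the diseased-minus-control mean difference on
#' the matrix's current scale (\code{logFC}), a residual variance
#' \eqn{s_g^2} with \eqn{d_g = n_1 + n_2 - 2} degrees of freedom, and a
#' moderated t-statistic in which \eqn{s_g^2} is shrunk toward a prior
#' variance \eqn{s_0^2} with prior degrees of freedom \eqn{d_0}:
#' \deqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g).}
#' The hyperparameters are estimated by the method of moments on
#' \eqn{e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)}: \eqn{d_0} solves
#' \eqn{\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d_g/2)} by monotone
#' root-finding, with \eqn{d_0 = \infty} when the right-hand side is not
#' positive, and \eqn{s_0^2 = \exp(\bar{e} + \psi(d_0/2) - \log(d_0/2))}
#' (or \eqn{\exp(\bar e)} for infinite \eqn{d_0}). Two-sided p-values come
#' from the t-distribution with \eqn{d_g + d_0} degrees of freedom. No
#' multiple-testing adjustment is applied anywhere.
#'
#' @param X \linkS4class{ExpressionMatrix} on the analysis scale (the
#'   pipelines run this on the compressed scale, so \code{logFC} is a group
#'   mean difference of linearly rescaled log intensities).
#' @param groups \linkS4class{SampleGroups}; both conditions need at least
#'   two samples.
#' @param d0Override force the prior degrees of freedom (0 recovers the
#'   ordinary pooled two-sample t-test); \code{NULL} estimates them.
#' @return A \linkS4class{DEAResult}.
#' @export
moderatedTTest <- function(X, groups, d0Override = NULL) {
    cond <- .checkGroups(X, groups, requireBoth = TRUE)
    v <- exprValues(X)
    ctl <- v[, cond == "control", drop = FALSE]
    dis <- v[, cond == "diseased", drop = FALSE]
    n1 <- ncol(ctl); n2 <- ncol(dis)
    dg <- n1 + n2 - 2
    if (dg < 1) stop("zero residual degrees of freedom")
    logfc <- rowMeans(dis) - rowMeans(ctl)
    ss <- (rowSums((ctl - rowMeans(ctl))^2) + rowSums((dis - rowMeans(dis))^2))
    s2 <- ss / dg
    if (any(s2 == 0)) {
        # guard against exactly-zero variances (e.g. duplicated columns);
        # substitute the smallest positive variance to keep logs finite
        floorv <- if (any(s2 > 0)) min(s2[s2 > 0]) else
            stop("all residual variances are zero")
        s2[s2 == 0] <- floorv
    }
    e <- log(s2) - digamma(dg / 2) + log(dg / 2)
    if (is.null(d0Override)) {
        evar <- var(e) - trigamma(dg / 2)
        if (is.na(evar) || evar <= 0) {
            d0 <- Inf
            s0sq <- exp(mean(e))
        } else {
            d0 <- 2 * .solveTrigamma(evar)
            s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
        }
    } else {
        d0 <- d0Override
        s0sq <- if (is.infinite(d0)) exp(mean(e))
            else if (d0 == 0) 0   # no shrinkage: prior carries no weight
            else exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
    stilde2 <- if (is.infinite(d0)) rep(s0sq, length(s2)) else
        (d0 * s0sq + dg * s2) / (d0 + dg)
    if (d0 == 0) stilde2 <- s2
    tstat <- logfc / (sqrt(stilde2) * sqrt(1 / n1 + 1 / n2))
    dft <- dg + d0
    p <- 2 * pt(-abs(tstat), df = dft)
    new("DEAResult",
        table = data.frame(feature_id = rownames(v), logFC = logfc,
                           t = tstat, P.Value = p, row.names = NULL),
        d0 = d0, s0sq = s0sq, dfResidual = dg)
}

#' Run DEA on a true and a predicted miRNA matrix
#'
#' Applies \code{\link{moderatedTTest}} to each matrix independently, on the
#' same (compressed) scale and with the same group assignments, so the two
#' result tables are directly comparable feature by feature.
#'
#' @param Ytrue,Ypred \linkS4class{ExpressionMatrix} objects with identical
#'   features and samples.
#' @param groups \linkS4class{SampleGroups}.
#' @return list with elements \code{true} and \code{pred}
#'   (\linkS4class{DEAResult} each).
#' @export
runDEAPair <- function(Ytrue, Ypred, groups) {
    if (!identical(featureIds(Ytrue), featureIds(Ypred)) ||
        !identical(sampleIds(Ytrue), sampleIds(Ypred)))
        stop("true and predicted matrices must share features and samples")
    list(true = moderatedTTest(Ytrue, groups),
         pred = moderatedTTest(Ypred, groups))
}

#' Write a DEAResult table as TSV
#' @param dea a \linkS4class{DEAResult}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDEATable <- function(dea, path) {
    write.table(deaTable(dea), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
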