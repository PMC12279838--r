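#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the reference distribution is the vector of row means of the
#' column-sorted matrix, and each value is replaced by the reference value
#' at its within-column rank. Ties within a column all receive the mean of
#' the reference values their rank positions span.
#'
#' @param X \linkS4class{ExpressionMatrix} on the log-intensity scale with
#'   at least two samples.
#' @return Quantile-normalized \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(c(5, 2, 3, 4, 1, 8), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' exprValues(quantileNormalize(ExpressionMatrix(m)))
#' @export
quantileNormalize <- function(X) {
    v <- exprValues(X)
    if (ncol(v) < 2L)
        stop("quantile normalization needs >=2 samples (nothing to normalize against)")
    ref <- rowMeans(apply(v, 2L, sort))
    out <- apply(v, 2L, function(col) {
        o <- order(col)
        res <- numeric(length(col))
        sorted <- col[o]
        # walk runs of tied values; each run gets the mean of the reference
        # quantiles it spans
        i <- 1L
        n <- length(col)
        while (i <= n) {
            j <- i
            while (j < n && sorted[j + 1L] == sorted[i]) j <- j + 1L
            res[o[i:j]] <- mean(ref[i:j])
            i <- j + 1L
        }
        res
    })
    dimnames(out) <- dimnames(v)
    ExpressionMatrix(out, scaleTag = scaleTag(X))
}

#' Log counts-per-million transform for count data
#'
#' Transforms non-negative counts to log2 counts-per-million with the
#' standard half-count offset:
#' \code{log2((count + 0.5) / (libsize + 1) * 1e6)}, where \code{libsize} is
#' the column sum. Precision weights are not computed; the transform is used
#' purely as a normalization step ahead of quantile normalization.
#'
#' @param counts \linkS4class{ExpressionMatrix} with \code{scaleTag
#'   "counts"} and non-negative values.
#' @return \linkS4class{ExpressionMatrix} on the log-intensity scale.
#' @export
voomLogCPM <- function(counts) {
    if (scaleTag(counts) != "counts")
        stop("voomLogCPM expects a matrix tagged 'counts'")
    v <- exprValues(counts)
    if (any(v < 0)) stop("counts must be non-negative")
    lib <- colSums(v)
    out <- log2(sweep(v + 0.5, 2L, lib + 1, "/") * 1e6)
    ExpressionMatrix(out, scaleTag = "log_intensity")
}

#' Fit global [0,1] compression parameters
#'
#' Records the matrix-wide minimum and maximum. Compression is global (one
#' min/max over all entries), preserving the relative expression profile
#' that the downstream correlations measure.
#'
#' @param X \linkS4class{ExpressionMatrix} with finite values.
#' @param label free-text provenance label stored with the params.
#' @param perFeature fit one min/max per feature row instead of the global
#'   default (available as an alternative; global scaling preserves
#'   relative expression levels across features).
#' @return A \linkS4class{CompressionParams}.
#' @export
fitCompression <- function(X, label = "unnamed", perFeature = FALSE) {
    v <- exprValues(X)
    if (perFeature) {
        lo <- apply(v, 1L, min); hi <- apply(v, 1L, max)
        if (any(hi == lo))
            stop("constant feature row(s): per-feature compression undefined")
    } else {
        lo <- min(v); hi <- max(v)
        if (hi == lo)
            stop("constant matrix: compression parameters are undefined")
    }
    new("CompressionParams", globalMin = lo, globalMax = hi, fittedOn = label)
}

#' Compress an expression matrix to [0,1]
#'
#' Applies \code{(value - min) / (max - min)}. When the params come from a
#' different matrix (cross-study mode) values may fall outside [0,1]; those
#' are clipped and the clip count is reported via a message and stored in
#' the \code{"clipped"} attribute of the returned values.
#'
#' @param X \linkS4class{ExpressionMatrix}.
#' @param params \linkS4class{CompressionParams}.
#' @return \linkS4class{ExpressionMatrix} with \code{scaleTag "compressed"}.
#' @export
applyCompression <- function(X, params) {
    v <- (exprValues(X) - params@globalMin) /
        (params@globalMax - params@globalMin)   # vectors recycle by row
    nclip <- sum(v < 0 | v > 1)
    if (nclip > 0) {
        message(nclip, " value(s) outside [0,1] clipped (foreign compression params)")
        v[v < 0] <- 0
        v[v > 1] <- 1
    }
    out <- ExpressionMatrix(v, scaleTag = "compressed")
    attr(out@values, "clipped") <- nclip
    out
}

#' Remove the lowest-expressed features
#'
#' Ranks features by their mean expression over all samples and removes the
#' \code{floor(fraction * n)} lowest; survivors keep their original order.
#' Features tied at the cutoff are removed in input order (earlier rows
#' first). With the default pipeline settings this filter is off; it gave
#' only situational benefit.
#'
#' @param X \linkS4class{ExpressionMatrix}.
#' @param fraction fraction of features to drop, in [0, 1).
#' @return Filtered \linkS4class{ExpressionMatrix}.
#' @export
filterLowExpressed <- function(X, fraction = 0.2) {
    if (fraction < 0 || fraction >= 1)
        stop("'fraction' must be in [0, 1)")
    v <- exprValues(X)
    k <- floor(fraction * nrow(v))
    if (k == 0L) return(X)
    if (k >= nrow(v)) stop("filter would remove all features")
    m <- rowMeans(v)
    drop <- order(m, seq_along(m))[seq_len(k)]
    keep <- sort(setdiff(seq_len(nrow(v)), drop))
    ExpressionMatrix(v[keep, , drop = FALSE], scaleTag = scaleTag(X))
}
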