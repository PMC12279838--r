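#' Pearson correlation with explicit degeneracy checks
#'
#' Standard Pearson r, erroring on the degenerate inputs (length < 3 or a
#' constant vector) for which the coefficient is undefined.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Pearson correlation coefficient.
#' @examples
#' pearsonR(c(1, 2, 3), c(1, 2, 4))
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y)) stop("x and y differ in length")
    if (length(x) < 3L) stop("need at least 3 observations")
    if (sd(x) == 0 || sd(y) == 0)
        stop("correlation undefined for a constant vector")
    cor(x, y, method = "pearson")
}

#' Sample-wise correlation between true and predicted profiles
#'
#' For each sample (column), the Pearson correlation across miRNA features
#' between the true and the predicted expression profile. Samples with a
#' constant profile in either matrix are recorded as \code{NA} rather than
#' failing the run.
#'
#' @param Ytrue,Ypred \linkS4class{ExpressionMatrix} objects of matching
#'   shape (features x samples).
#' @return named numeric vector, one r (or NA) per sample.
#' @export
samplewiseCorrelation <- function(Ytrue, Ypred) {
    vt <- exprValues(Ytrue); vp <- exprValues(Ypred)
    if (!all(dim(vt) == dim(vp)))
        stop("true and predicted matrices differ in shape")
    r <- vapply(seq_len(ncol(vt)), function(s) {
        a <- vt[, s]; b <- vp[, s]
        if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
    }, numeric(1))
    setNames(r, colnames(vt))
}

#' Concordance of DEA results between true and predicted data
#'
#' Correlates the log2 fold changes and the raw p-values of two
#' \linkS4class{DEAResult} objects over their shared features. Features
#' with a non-finite statistic in either result are dropped pairwise.
#' p-values are correlated raw by default; set \code{negLog10P = TRUE} to
#' correlate \code{-log10(p)} instead.
#'
#' @param deaTrue,deaPred \linkS4class{DEAResult} objects over the same
#'   features.
#' @param negLog10P correlate \code{-log10} transformed p-values.
#' @return list with \code{rLogFC}, \code{rPValue} and
#'   \code{nFeaturesCompared}.
#' @export
deaConcordance <- function(deaTrue, deaPred, negLog10P = FALSE) {
    tt <- deaTable(deaTrue); tp <- deaTable(deaPred)
    if (!identical(tt$feature_id, tp$feature_id))
        stop("DEA results cover different feature sets")
    keep <- is.finite(tt$logFC) & is.finite(tp$logFC) &
        is.finite(tt$P.Value) & is.finite(tp$P.Value)
    n <- sum(keep)
    if (n <= 2L) stop("fewer than 3 features with defined statistics")
    pt_ <- tt$P.Value[keep]; pp_ <- tp$P.Value[keep]
    if (negLog10P) { pt_ <- -log10(pt_); pp_ <- -log10(pp_) }
    list(rLogFC = pearsonR(tt$logFC[keep], tp$logFC[keep]),
         rPValue = pearsonR(pt_, pp_),
         nFeaturesCompared = as.integer(n))
}

# assemble a ConcordanceReport from its pieces
.concordanceReport <- function(perSampleR, conc, metadata) {
    new("ConcordanceReport", perSampleR = perSampleR,
        medianSampleR = median(perSampleR, na.rm = TRUE),
        rLogFC = conc$rLogFC, rPValue = conc$rPValue,
        nFeaturesCompared = conc$nFeaturesCompared, metadata = metadata)
}

#' Serialize / restore a ConcordanceReport
#'
#' \code{writeConcordanceReport} writes the report as JSON (plus a TSV of
#' per-sample correlations next to it); \code{readConcordanceReport}
#' restores a lossless copy from the JSON.
#'
#' @param report a \linkS4class{ConcordanceReport}.
#' @param path JSON output path; the TSV is written as
#'   \code{<path>.samples.tsv}.
#' @return \code{path} (write) or the restored report (read).
#' @export
writeConcordanceReport <- function(report, path) {
    jsonlite::write_json(
        list(per_sample_r = as.list(report@perSampleR),
             median_sample_r = report@medianSampleR,
             r_logfc = report@rLogFC, r_pvalue = report@rPValue,
             n_features_compared = report@nFeaturesCompared,
             metadata = report@metadata),
        path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
    write.table(data.frame(sample_id = names(report@perSampleR),
                           r = report@perSampleR),
                paste0(path, ".samples.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' @rdname writeConcordanceReport
#' @export
readConcordanceReport <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    psr <- unlist(j$per_sample_r)
    if (is.null(psr)) psr <- numeric()
    md <- as.list(j$metadata)
    new("ConcordanceReport", perSampleR = psr,
        medianSampleR = j$median_sample_r, rLogFC = j$r_logfc,
        rPValue = j$r_pvalue,
        nFeaturesCompared = as.integer(j$n_features_compared),
        metadata = md)
}

#' Export scatter data of true vs. predicted DEA statistics
#'
#' Writes the per-feature pairs (logFC true/predicted, p-value
#' true/predicted) as TSV for external plotting.
#'
#' @param deaTrue,deaPred \linkS4class{DEAResult} objects.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeScatterData <- function(deaTrue, deaPred, path) {
    tt <- deaTable(deaTrue); tp <- deaTable(deaPred)
    write.table(data.frame(feature_id = tt$feature_id,
                           logFC_true = tt$logFC, logFC_pred = tp$logFC,
                           p_true = tt$P.Value, p_pred = tp$P.Value),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
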