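#' Mean absolute first-layer weight per mRNA input
#'
#' For each input (mRNA) feature, the mean of the absolute weights with
#' which it is forwarded to the first hidden layer. Absolute values are
#' used because signed means of symmetric weight distributions cancel and
#' would rank noise; set \code{signed = TRUE} for raw signed means.
#'
#' @param model a trained \linkS4class{MLPModel}.
#' @param signed use signed instead of absolute weights.
#' @return named numeric vector, one mean weight per input feature.
#' @export
firstLayerMeanWeights <- function(model, signed = FALSE) {
    if (!is(model, "MLPModel"))
        stop("first-layer weights are only defined for MLP models")
    W1 <- model@weights[[1L]]$W
    w <- if (signed) rowMeans(W1) else rowMeans(abs(W1))
    setNames(w, model@inputFeatureIds)
}

#' Transcription-factor enrichment among top-weighted predictors
#'
#' Takes the \code{ceiling(topFraction * n)} input features with the
#' largest mean first-layer weight (ties broken by input order) and reports
#' the proportion of transcription factors in that top set and in the full
#' predictor set. Feature-to-TF matching is case-insensitive.
#'
#' @param weights named per-input weights from
#'   \code{\link{firstLayerMeanWeights}}.
#' @param tfList character vector of TF symbols (see
#'   \code{\link{readTFList}}).
#' @param topFraction fraction of inputs forming the top set (default 5%).
#' @return list of class \code{weightReport}: \code{topFeatureIds},
#'   \code{tfPropTop}, \code{tfPropAll}, \code{topFraction}, \code{nTop}.
#' @export
tfEnrichment <- function(weights, tfList, topFraction = 0.05) {
    stopifnot(topFraction > 0, topFraction <= 1)
    ids <- names(weights)
    if (is.null(ids)) stop("'weights' must be named by feature ID")
    n <- length(weights)
    # tolerance guards against floating-point overshoot (0.05 * 100 > 5)
    k <- max(1L, as.integer(ceiling(topFraction * n - 1e-9)))
    top <- ids[order(-weights, seq_len(n))[seq_len(k)]]
    tfs <- unique(toupper(tfList))
    isTF <- function(x) toupper(x) %in% tfs
    structure(list(topFeatureIds = top,
                   tfPropTop = if (length(tfs)) mean(isTF(top)) else 0,
                   tfPropAll = if (length(tfs)) mean(isTF(ids)) else 0,
                   topFraction = topFraction, nTop = k),
              class = "weightReport")
}

#' @export
print.weightReport <- function(x, ...) {
    cat(sprintf("Top %.1f%% predictors (n = %d): %.2f%% TFs (background %.2f%%)\n",
                100 * x$topFraction, x$nTop, 100 * x$tfPropTop,
                100 * x$tfPropAll))
    invisible(x)
}

#' Write a weight report as TSV + JSON
#'
#' @param weights per-input mean weights.
#' @param report a \code{weightReport} from \code{\link{tfEnrichment}}.
#' @param prefix output prefix; writes \code{<prefix>.tsv} (per-feature
#'   weights, flagging top-set membership) and \code{<prefix>.json}.
#' @return \code{prefix}, invisibly.
#' @export
writeWeightReport <- function(weights, report, prefix) {
    write.table(data.frame(feature_id = names(weights), mean_weight = weights,
                           in_top = names(weights) %in% report$topFeatureIds),
                paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(list(tf_prop_top = report$tfPropTop,
                              tf_prop_all = report$tfPropAll,
                              top_fraction = report$topFraction,
                              n_top = report$nTop),
                         paste0(prefix, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(prefix)
}
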