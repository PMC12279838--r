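#' @import methods
#' @importFrom stats rnorm runif var cor pt sd quantile median setNames
#' @importFrom utils read.delim write.table head
#' @useDynLib crossmir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom Matrix sparseMatrix Diagonal crossprod summary
NULL

.SCALE_TAGS <- c("counts", "log_intensity", "compressed")
.CONDITIONS <- c("control", "diseased")

#' ExpressionMatrix: a features x samples expression matrix with a scale tag
#'
#' Thin S4 container for a numeric expression matrix. Rows are molecular
#' features (mRNAs or miRNAs), columns are samples. The scale tag records
#' whether values are raw counts, log-scale intensities, or globally
#' compressed to [0,1]; downstream operations check it so that, e.g., the
#' log-CPM transform is only applied to counts.
#'
#' @slot values numeric matrix with unique, non-empty dimnames
#'   (rownames = feature IDs, colnames = sample IDs); all values finite.
#' @slot scaleTag one of \code{"counts"}, \code{"log_intensity"},
#'   \code{"compressed"}.
#'
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
    representation(values = "matrix", scaleTag = "character"))

setValidity("ExpressionMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v))
        msg <- c(msg, "'values' must be a numeric matrix")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "'values' must carry feature (row) and sample (column) names")
    else {
        if (anyDuplicated(rownames(v)))
            msg <- c(msg, "feature IDs must be unique")
        if (anyDuplicated(colnames(v)))
            msg <- c(msg, "sample IDs must be unique")
    }
    if (length(object@scaleTag) != 1L || !object@scaleTag %in% .SCALE_TAGS)
        msg <- c(msg, sprintf("scaleTag must be one of: %s",
                              paste(.SCALE_TAGS, collapse = ", ")))
    if (is.numeric(v) && length(v) && !all(is.finite(v)))
        msg <- c(msg, "'values' must be finite (drop non-finite rows at construction)")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' Rows containing any non-finite value are dropped with a message reporting
#' the count; no imputation is performed.
#'
#' @param values numeric matrix (features x samples) with dimnames.
#' @param scaleTag \code{"counts"}, \code{"log_intensity"} or
#'   \code{"compressed"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m, "log_intensity")
#' @export
ExpressionMatrix <- function(values, scaleTag = "log_intensity") {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    bad <- !apply(is.finite(values), 1L, all)
    if (any(bad)) {
        message(sum(bad), " feature row(s) with non-finite values dropped")
        values <- values[!bad, , drop = FALSE]
    }
    if (nrow(values) == 0L)
        stop("expression matrix is empty after dropping non-finite rows")
    new("ExpressionMatrix", values = values, scaleTag = scaleTag)
}

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix: %d features x %d samples [%s]\n",
                nrow(object@values), ncol(object@values), object@scaleTag))
    cat("features:", paste(head(rownames(object@values), 4L), collapse = ", "),
        if (nrow(object@values) > 4L) "..." else "", "\n")
    cat("samples: ", paste(head(colnames(object@values), 4L), collapse = ", "),
        if (ncol(object@values) > 4L) "..." else "", "\n")
})

#' SampleGroups: sample-to-condition assignments
#'
#' Maps each sample ID to a two-group condition label, \code{"control"} or
#' \code{"diseased"}.
#'
#' @slot sampleIds character vector of unique sample IDs.
#' @slot condition factor with levels \code{control}, \code{diseased},
#'   parallel to \code{sampleIds}.
#' @exportClass SampleGroups
setClass("SampleGroups",
    representation(sampleIds = "character", condition = "factor"))

setValidity("SampleGroups", function(object) {
    msg <- character()
    if (anyDuplicated(object@sampleIds))
        msg <- c(msg, "sample IDs must be unique")
    if (length(object@sampleIds) != length(object@condition))
        msg <- c(msg, "sampleIds and condition lengths differ")
    if (!identical(levels(object@condition), .CONDITIONS))
        msg <- c(msg, "condition levels must be exactly {control, diseased}")
    if (length(msg)) msg else TRUE
})

#' Construct SampleGroups
#'
#' @param condition named character vector or factor; names are sample IDs,
#'   values are \code{"control"} or \code{"diseased"}.
#' @return A \linkS4class{SampleGroups}.
#' @examples
#' SampleGroups(c(s1 = "control", s2 = "diseased"))
#' @export
SampleGroups <- function(condition) {
    ids <- names(condition)
    if (is.null(ids)) stop("'condition' must be named by sample ID")
    cond <- as.character(condition)
    bad <- setdiff(unique(cond), .CONDITIONS)
    if (length(bad))
        stop("unknown condition label(s): ", paste(bad, collapse = ", "),
             "; allowed labels are: ", paste(.CONDITIONS, collapse = ", "))
    new("SampleGroups", sampleIds = ids,
        condition = factor(cond, levels = .CONDITIONS))
}

setMethod("show", "SampleGroups", function(object) {
    tb <- table(object@condition)
    cat(sprintf("SampleGroups: %d samples (%d control, %d diseased)\n",
                length(object@sampleIds), tb[["control"]], tb[["diseased"]]))
})

#' CompressionParams: [0,1] compression parameters
#'
#' @slot globalMin,globalMax extremes the compression maps to 0/1 — scalars
#'   for the default matrix-wide fit, or per-feature vectors.
#' @slot fittedOn free-text label of the matrix the params were fitted on.
#' @exportClass CompressionParams
setClass("CompressionParams",
    representation(globalMin = "numeric", globalMax = "numeric",
                   fittedOn = "character"))

setValidity("CompressionParams", function(object) {
    if (length(object@globalMin) != length(object@globalMax))
        return("globalMin and globalMax lengths differ")
    if (any(object@globalMax <= object@globalMin))
        "globalMax must exceed globalMin" else TRUE
})

#' DEAResult: two-group differential expression with moderated t
#'
#' @slot table data.frame with columns \code{feature_id}, \code{logFC}
#'   (diseased minus control group mean on the analysis scale), \code{t}
#'   (moderated t) and \code{P.Value} (raw two-sided p; no multiplicity
#'   adjustment is ever applied).
#' @slot d0 prior degrees of freedom (may be \code{Inf}).
#' @slot s0sq prior variance.
#' @slot dfResidual residual degrees of freedom per feature.
#' @exportClass DEAResult
setClass("DEAResult",
    representation(table = "data.frame", d0 = "numeric", s0sq = "numeric",
                   dfResidual = "numeric"))

setMethod("show", "DEAResult", function(object) {
    cat(sprintf("DEAResult: %d features; prior df d0 = %s, prior variance s0^2 = %.4g\n",
                nrow(object@table),
                if (is.infinite(object@d0)) "Inf" else sprintf("%.3g", object@d0),
                object@s0sq))
})

#' ConcordanceReport: true-vs-predicted miRNA concordance
#'
#' @slot perSampleR Pearson r per sample between true and predicted miRNA
#'   profiles (NA where a profile is constant).
#' @slot medianSampleR median of the finite per-sample correlations.
#' @slot rLogFC Pearson r of true vs. predicted log2 fold changes.
#' @slot rPValue Pearson r of true vs. predicted raw p-values.
#' @slot nFeaturesCompared number of features entering the DEA correlations.
#' @slot metadata run metadata (mode, model kind, augmentation, condition
#'   handling, seed, ...).
#' @exportClass ConcordanceReport
setClass("ConcordanceReport",
    representation(perSampleR = "numeric", medianSampleR = "numeric",
                   rLogFC = "numeric", rPValue = "numeric",
                   nFeaturesCompared = "integer", metadata = "list"))

setMethod("show", "ConcordanceReport", function(object) {
    cat("ConcordanceReport\n")
    cat(sprintf("  median sample-wise r: %.4f (%d samples)\n",
                object@medianSampleR, length(object@perSampleR)))
    cat(sprintf("  r(log2FC):  %.4f\n", object@rLogFC))
    cat(sprintf("  r(p-value): %.4f\n", object@rPValue))
    cat(sprintf("  features compared: %d\n", object@nFeaturesCompared))
    if (length(object@metadata))
        cat("  run:", paste(names(object@metadata), unlist(lapply(object@metadata, format)),
                            sep = "=", collapse = " "), "\n")
})

#' MLPModel: trained multi-output neural network predictor
#'
#' Fitted feed-forward network mapping a compressed mRNA profile to a
#' compressed miRNA profile. Weights are stored explicitly so the first
#' layer can be inspected for interpretation.
#'
#' @slot inputFeatureIds,outputFeatureIds feature ID vectors.
#' @slot weights list of layer weight matrices \code{W} (in x out) and bias
#'   vectors \code{b}.
#' @slot batchnorm list per hidden layer: \code{gamma}, \code{beta},
#'   \code{mean}, \code{var} (running statistics used at inference), or
#'   length 0 when batch normalization is disabled.
#' @slot config the \code{\link{mlpConfig}} the model was trained with.
#' @slot history data.frame of per-epoch \code{train_loss}, \code{val_loss},
#'   \code{learning_rate}.
#' @exportClass MLPModel
setClass("MLPModel",
    representation(inputFeatureIds = "character", outputFeatureIds = "character",
                   weights = "list", batchnorm = "list", config = "list",
                   history = "data.frame"))

setMethod("show", "MLPModel", function(object) {
    widths <- vapply(object@weights, function(l) ncol(l$W), integer(1))
    cat(sprintf("MLPModel: %d inputs -> [%s] -> %d outputs; trained %d epochs\n",
                length(object@inputFeatureIds),
                paste(widths[-length(widths)], collapse = ", "),
                length(object@outputFeatureIds), nrow(object@history)))
})

#' LassoModelSet: per-miRNA LASSO regularization paths
#'
#' One L1-regularization path per miRNA, all sharing the same mRNA predictor
#' set and path length. miRNAs with a degenerate (constant) response are
#' recorded as skipped and predicted at their training mean.
#'
#' @slot predictorIds shared mRNA predictor IDs.
#' @slot responseIds miRNA IDs (one path or skip record each).
#' @slot paths named list; for fitted miRNAs a list with \code{lambda}
#'   (strictly decreasing), \code{beta} (sparse predictors x nlambda matrix,
#'   original scale), \code{intercept} (per lambda), \code{trainMean}; for
#'   skipped miRNAs a list with \code{skipped = TRUE} and \code{trainMean}.
#' @slot nlambda path length.
#' @exportClass LassoModelSet
setClass("LassoModelSet",
    representation(predictorIds = "character", responseIds = "character",
                   paths = "list", nlambda = "integer"))

setMethod("show", "LassoModelSet", function(object) {
    nskip <- sum(vapply(object@paths, function(p) isTRUE(p$skipped), logical(1)))
    cat(sprintf("LassoModelSet: %d miRNA paths (%d skipped), %d predictors, %d lambdas\n",
                length(object@paths), nskip, length(object@predictorIds),
                object@nlambda))
})

#' SimTruth: ground truth of a simulated paired dataset
#'
#' @slot targetMap list mapping each miRNA ID to the integer indices of its
#'   target mRNAs.
#' @slot deMirnaIds IDs of the differentially expressed miRNAs.
#' @slot deSign named +1/-1 vector over DE miRNAs (direction in diseased).
#' @slot trueMirnaLogFC expected log-scale fold change per miRNA
#'   (delta * sign for DE miRNAs, 0 otherwise).
#' @slot mirnaBaseline,mrnaBaseline per-feature baseline log intensities.
#' @exportClass SimTruth
setClass("SimTruth",
    representation(targetMap = "list", deMirnaIds = "character",
                   deSign = "numeric", trueMirnaLogFC = "numeric",
                   mirnaBaseline = "numeric", mrnaBaseline = "numeric"))

setMethod("show", "SimTruth", function(object) {
    cat(sprintf("SimTruth: %d miRNAs (%d DE), %d target mRNAs per miRNA\n",
                length(object@targetMap), length(object@deMirnaIds),
                length(object@targetMap[[1]])))
})
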