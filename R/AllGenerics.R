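#' Accessors for ExpressionMatrix and friends
#'
#' @param object an object of the corresponding class.
#' @name accessors
NULL

#' @rdname accessors
#' @return \code{featureIds}: character vector of feature IDs.
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setMethod("featureIds", "ExpressionMatrix", function(object) rownames(object@values))

#' @rdname accessors
#' @return \code{sampleIds}: character vector of sample IDs.
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(object) colnames(object@values))

#' @rdname accessors
#' @export
setMethod("sampleIds", "SampleGroups", function(object) object@sampleIds)

#' @rdname accessors
#' @return \code{exprValues}: the numeric matrix (features x samples).
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(object) object@values)

#' @rdname accessors
#' @return \code{scaleTag}: the declared scale of the values.
#' @export
setGeneric("scaleTag", function(object) standardGeneric("scaleTag"))

#' @rdname accessors
#' @export
setMethod("scaleTag", "ExpressionMatrix", function(object) object@scaleTag)

#' @rdname accessors
#' @return \code{conditions}: factor of condition labels named by sample ID.
#' @export
setGeneric("conditions", function(object) standardGeneric("conditions"))

#' @rdname accessors
#' @export
setMethod("conditions", "SampleGroups", function(object)
    setNames(object@condition, object@sampleIds))

#' @rdname accessors
#' @return \code{deaTable}: data.frame with feature_id, logFC, t, P.Value.
#' @export
setGeneric("deaTable", function(object) standardGeneric("deaTable"))

#' @rdname accessors
#' @export
setMethod("deaTable", "DEAResult", function(object) object@table)

#' Predict miRNA expression from mRNA profiles
#'
#' Applies a trained predictor (MLP or LASSO model set) to a compressed mRNA
#' expression matrix and returns the predicted miRNA matrix.
#'
#' @param object a trained \linkS4class{MLPModel} or
#'   \linkS4class{LassoModelSet}.
#' @param X \linkS4class{ExpressionMatrix} of mRNA predictors whose feature
#'   IDs match the model's input features in order.
#' @param ... method-specific arguments; for LASSO, \code{lambdaChoice}.
#' @return An \linkS4class{ExpressionMatrix} of predicted miRNA values
#'   (compressed scale), features x samples.
#' @export
setGeneric("predictExpression", function(object, X, ...)
    standardGeneric("predictExpression"))
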