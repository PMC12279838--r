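#' Configuration for the multi-output neural network
#'
#' Defaults follow the reference setting used throughout the package: four
#' hidden dense layers of 1024, 512, 256 and 128 units, each followed by
#' batch normalization, ReLU and dropout 0.4, with an L2 penalty on the
#' hidden-layer kernels; linear output; mean-squared-error loss; Adam at
#' learning rate 0.001 with a reduce-on-plateau schedule (factor 0.5,
#' patience 5 epochs on validation loss, floor 1e-6); at most 150 epochs,
#' batch size 32, validation split 20%.
#'
#' @param hiddenSizes integer vector of hidden-layer widths.
#' @param batchnormAfterDense apply batch normalization between each dense
#'   layer and its ReLU activation.
#' @param l2Coeff L2 penalty coefficient on hidden-layer kernels (the loss
#'   adds \code{l2Coeff * sum(W^2)}).
#' @param dropoutRate dropout rate in [0, 1).
#' @param learningRate initial Adam learning rate.
#' @param lrPlateauFactor multiplicative learning-rate reduction on plateau.
#' @param lrPlateauPatience epochs without validation-loss improvement
#'   before reducing the rate.
#' @param minLearningRate learning-rate floor.
#' @param maxEpochs maximum training epochs (no early stopping).
#' @param batchSize minibatch size.
#' @param validationSplit fraction of samples held out as the validation
#'   set (the last fraction of the seeded shuffle), in (0, 1).
#' @param seed integer seed fixing initialization, shuffling and dropout.
#' @return validated list of class \code{mlpConfig}.
#' @export
mlpConfig <- function(hiddenSizes = c(1024L, 512L, 256L, 128L),
                      batchnormAfterDense = TRUE, l2Coeff = 1e-4,
                      dropoutRate = 0.4, learningRate = 0.001,
                      lrPlateauFactor = 0.5, lrPlateauPatience = 5L,
                      minLearningRate = 1e-6, maxEpochs = 150L,
                      batchSize = 32L, validationSplit = 0.2, seed = 1L) {
    stopifnot(length(hiddenSizes) >= 1, all(hiddenSizes >= 1),
              dropoutRate >= 0, dropoutRate < 1,
              validationSplit > 0, validationSplit < 1,
              l2Coeff >= 0, learningRate > 0, maxEpochs >= 1, batchSize >= 1)
    structure(list(hiddenSizes = as.integer(hiddenSizes),
                   activation = "relu",
                   batchnormAfterDense = isTRUE(batchnormAfterDense),
                   l2Coeff = l2Coeff, dropoutRate = dropoutRate,
                   outputActivation = "linear", loss = "mse", metric = "mae",
                   optimizer = "adam", learningRate = learningRate,
                   lrPlateauFactor = lrPlateauFactor,
                   lrPlateauPatience = as.integer(lrPlateauPatience),
                   minLearningRate = minLearningRate,
                   maxEpochs = as.integer(maxEpochs),
                   batchSize = as.integer(batchSize),
                   validationSplit = validationSplit,
                   bnEpsilon = 1e-3, bnMomentum = 0.99, adamEpsilon = 1e-7,
                   seed = as.integer(seed)),
              class = "mlpConfig")
}

#' Describe the network architecture for given input/output widths
#'
#' Returns the layer-by-layer architecture the trainer will build, without
#' fitting anything; useful for introspection and sanity checks.
#'
#' @param nIn number of input (mRNA) features.
#' @param nOut number of output (miRNA) features.
#' @param cfg an \code{\link{mlpConfig}}.
#' @return list of class \code{mlpArchitecture} with a \code{layers}
#'   data.frame (type, width) and the config.
#' @examples
#' buildMLP(14977, 499)$widths
#' @export
buildMLP <- function(nIn, nOut, cfg = mlpConfig()) {
    stopifnot(nIn >= 1, nOut >= 1)
    blocks <- lapply(cfg$hiddenSizes, function(h) {
        c("dense", if (cfg$batchnormAfterDense) "batchnorm", "relu",
          if (cfg$dropoutRate > 0) "dropout")
    })
    layers <- data.frame(
        type = c("input", unlist(blocks), "dense_linear"),
        width = as.integer(c(nIn,
            unlist(lapply(seq_along(cfg$hiddenSizes), function(i)
                rep(cfg$hiddenSizes[i], length(blocks[[i]])))), nOut)))
    structure(list(nIn = as.integer(nIn), nOut = as.integer(nOut),
                   widths = cfg$hiddenSizes, layers = layers, config = cfg),
              class = "mlpArchitecture")
}

#' @export
print.mlpArchitecture <- function(x, ...) {
    cat(sprintf("MLP architecture: %d -> [%s] -> %d\n", x$nIn,
                paste(x$widths, collapse = ", "), x$nOut))
    invisible(x)
}

#' Train the multi-output neural network
#'
#' Fits the mRNA-to-miRNA regression network on compressed expression
#' matrices. Samples are shuffled once under the config seed; the last
#' \code{validationSplit} fraction forms the validation set monitored by the
#' plateau schedule. Training is single-threaded and fully reproducible
#' given the seed.
#'
#' @param X \linkS4class{ExpressionMatrix} of compressed mRNA predictors.
#' @param Y \linkS4class{ExpressionMatrix} of compressed miRNA responses,
#'   same samples in the same order.
#' @param cfg an \code{\link{mlpConfig}}.
#' @return A trained \linkS4class{MLPModel} (its \code{history} slot holds
#'   per-epoch train/validation loss and learning rate).
#' @export
trainMLP <- function(X, Y, cfg = mlpConfig()) {
    stopifnot(inherits(cfg, "mlpConfig"))
    if (!identical(sampleIds(X), sampleIds(Y)))
        stop("X and Y must share sample IDs in the same order")
    n <- length(sampleIds(X))
    nval <- floor(cfg$validationSplit * n)
    if (nval < 1L || n - nval < 1L)
        stop("too few samples for a ", cfg$validationSplit,
             " validation split (n = ", n,
             "); consider augmenting the training data")
    Xm <- t(exprValues(X))  # samples x features
    Ym <- t(exprValues(Y))
    fit <- withr::with_seed(cfg$seed, {
        perm <- sample.int(n)
        tr <- perm[seq_len(n - nval)]
        va <- perm[(n - nval + 1L):n]
        .cpp_mlp_train(Xm[tr, , drop = FALSE], Ym[tr, , drop = FALSE],
                       Xm[va, , drop = FALSE], Ym[va, , drop = FALSE],
                       cfg$hiddenSizes, cfg$batchnormAfterDense,
                       cfg$l2Coeff, cfg$dropoutRate, cfg$learningRate,
                       cfg$lrPlateauFactor, cfg$lrPlateauPatience,
                       cfg$minLearningRate, cfg$maxEpochs, cfg$batchSize,
                       cfg$bnEpsilon, cfg$bnMomentum, cfg$adamEpsilon)
    })
    nlay <- length(fit$W)
    weights <- lapply(seq_len(nlay), function(l)
        list(W = fit$W[[l]], b = as.numeric(fit$b[[l]])))
    bn <- if (cfg$batchnormAfterDense)
        lapply(seq_len(nlay - 1L), function(l)
            list(gamma = as.numeric(fit$gamma[[l]]),
                 beta = as.numeric(fit$beta[[l]]),
                 mean = as.numeric(fit$rmean[[l]]),
                 var = as.numeric(fit$rvar[[l]])))
    else list()
    new("MLPModel", inputFeatureIds = featureIds(X),
        outputFeatureIds = featureIds(Y), weights = weights, batchnorm = bn,
        config = unclass(cfg), history = as.data.frame(fit$history))
}

# rebuild the C++ parameter list from an MLPModel
.mlpParamList <- function(model) {
    li <- list(W = lapply(model@weights, `[[`, "W"),
               b = lapply(model@weights, function(l) rbind(l$b)),
               use_bn = length(model@batchnorm) > 0)
    if (li$use_bn) {
        li$gamma <- lapply(model@batchnorm, function(l) rbind(l$gamma))
        li$beta <- lapply(model@batchnorm, function(l) rbind(l$beta))
        li$rmean <- lapply(model@batchnorm, function(l) rbind(l$mean))
        li$rvar <- lapply(model@batchnorm, function(l) rbind(l$var))
    }
    li
}

#' @describeIn predictExpression inference-mode forward pass of the trained
#'   network (batch normalization uses running statistics; dropout off);
#'   deterministic and sample-equivariant.
#' @export
setMethod("predictExpression", "MLPModel", function(object, X, ...) {
    if (!identical(featureIds(X), object@inputFeatureIds))
        stop("feature IDs of X do not match the model's input features")
    pred <- .cpp_mlp_predict(.mlpParamList(object), t(exprValues(X)),
                             object@config$bnEpsilon)
    out <- t(pred)
    dimnames(out) <- list(object@outputFeatureIds, sampleIds(X))
    ExpressionMatrix(out, scaleTag = "compressed")
})

#' Save / load a trained MLP model
#'
#' The fitted state is serialized with \code{saveRDS}; a human-readable JSON
#' sidecar (\code{<path>.json}) records the feature IDs and training
#' configuration.
#'
#' @param model a trained \linkS4class{MLPModel}.
#' @param path checkpoint path (e.g. \code{model.rds}).
#' @return \code{path} (save) or the \linkS4class{MLPModel} (load).
#' @export
saveMLPModel <- function(model, path) {
    saveRDS(model, path)
    jsonlite::write_json(list(input_feature_ids = model@inputFeatureIds,
                              output_feature_ids = model@outputFeatureIds,
                              config = model@config),
                         paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname saveMLPModel
#' @export
loadMLPModel <- function(path) readRDS(path)
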