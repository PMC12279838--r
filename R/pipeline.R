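#' Configuration for a full prediction run
#'
#' Bundles every stage choice of a within-data or cross-study run. Config
#' contradictions (e.g. a joint LASSO fit without the explicit override;
#' LASSO models are fitted separately per condition by default) are
#' rejected here, before any computation.
#'
#' @param mode \code{"within"} (train and evaluate on the same dataset) or
#'   \code{"cross_study"} (train on one study, predict another).
#' @param model \code{"mlp"} or \code{"lasso"}.
#' @param conditionHandling \code{"joint"} (one model for both conditions)
#'   or \code{"separate"} (one model per condition).
#' @param augment an \code{\link{augmentConfig}}, or \code{NULL} to disable
#'   augmentation.
#' @param filterEnabled,filterFraction drop the lowest-expressed feature
#'   fraction from both matrices before compression (off by default; gave
#'   only situational benefit).
#' @param compressPerFeature compress each feature to [0,1] separately
#'   instead of the default global min/max (the default preserves the
#'   profile shape the correlations measure).
#' @param lambdaChoice LASSO path point used for prediction,
#'   \code{"minimal"} or \code{"tenth_largest"}.
#' @param nlambda,lambdaRatio LASSO path settings.
#' @param mlp an \code{\link{mlpConfig}} (its seed is re-derived from
#'   \code{seed}).
#' @param allowJointLasso explicit override permitting a joint LASSO fit.
#' @param outputDir optional directory for run artifacts (config echo, log,
#'   reports, DEA tables).
#' @param seed integer master seed; every stochastic stage derives its seed
#'   from it.
#' @param verbose log progress via \code{message()}.
#' @return validated list of class \code{runConfig}.
#' @export
runConfig <- function(mode = c("within", "cross_study"),
                      model = c("mlp", "lasso"),
                      conditionHandling = c("separate", "joint"),
                      augment = augmentConfig(),
                      filterEnabled = FALSE, filterFraction = 0.2,
                      compressPerFeature = FALSE,
                      lambdaChoice = c("minimal", "tenth_largest"),
                      nlambda = 100L, lambdaRatio = 0.01,
                      mlp = mlpConfig(), allowJointLasso = FALSE,
                      outputDir = NULL, seed = 1L, verbose = FALSE) {
    mode <- match.arg(mode)
    model <- match.arg(model)
    conditionHandling <- match.arg(conditionHandling)
    lambdaChoice <- match.arg(lambdaChoice)
    if (!is.null(augment) && !inherits(augment, "augmentConfig"))
        stop("'augment' must be an augmentConfig() or NULL")
    stopifnot(inherits(mlp, "mlpConfig"))
    if (model == "lasso" && conditionHandling == "joint" && !allowJointLasso)
        stop("joint LASSO fitting requires allowJointLasso = TRUE ",
             "(LASSO models are fitted separately per condition)")
    structure(list(mode = mode, model = model,
                   conditionHandling = conditionHandling, augment = augment,
                   filterEnabled = isTRUE(filterEnabled),
                   filterFraction = filterFraction,
                   compressPerFeature = isTRUE(compressPerFeature),
                   lambdaChoice = lambdaChoice, nlambda = as.integer(nlambda),
                   lambdaRatio = lambdaRatio, mlp = mlp,
                   allowJointLasso = isTRUE(allowJointLasso),
                   outputDir = outputDir, seed = as.integer(seed),
                   verbose = isTRUE(verbose)),
              class = "runConfig")
}

# run-scoped logger: collects lines, optionally echoes them
.makeLog <- function(verbose) {
    lines <- character()
    log <- function(...) {
        line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                        paste0(...))
        lines[[length(lines) + 1L]] <<- line
        if (verbose) message(line)
        invisible(line)
    }
    list(log = log, lines = function() unlist(lines))
}

# filter + compress one matrix; returns compressed matrix and params
.prepMatrix <- function(X, cfg, log, label) {
    if (cfg$filterEnabled) {
        X <- filterLowExpressed(X, cfg$filterFraction)
        log(label, ": ", length(featureIds(X)), " features after filtering")
    }
    params <- fitCompression(X, label = label,
                             perFeature = cfg$compressPerFeature)
    list(X = applyCompression(X, params), params = params)
}

# train the configured model(s); returns a named list of models
# ("all" for joint handling, one entry per condition for separate)
.trainModels <- function(Xc, Yc, groups, cfg, log) {
    mlpWithSeed <- function(seed) {
        m <- cfg$mlp; m$seed <- as.integer(seed); m
    }
    fit <- function(X, Y, seedOffset) {
        if (cfg$model == "mlp")
            trainMLP(X, Y, mlpWithSeed(cfg$seed + seedOffset))
        else
            fitLassoPerMirna(X, Y, nlambda = cfg$nlambda,
                             ratio = cfg$lambdaRatio)
    }
    if (cfg$conditionHandling == "joint") {
        log("training joint ", cfg$model, " model on ",
            length(sampleIds(Xc)), " samples")
        list(all = fit(Xc, Yc, 1L))
    } else {
        cond <- conditions(groups)[sampleIds(Xc)]
        models <- lapply(seq_along(.CONDITIONS), function(i) {
            keep <- names(cond)[cond == .CONDITIONS[i]]
            log("training ", .CONDITIONS[i], " ", cfg$model, " model on ",
                length(keep), " samples")
            fit(.subsetSamples(Xc, keep), .subsetSamples(Yc, keep), i)
        })
        names(models) <- .CONDITIONS
        models
    }
}

# predict the given (original) samples with the condition-matched models
.predictSamples <- function(models, Xc, groups, cfg) {
    predictOne <- function(model, X) {
        if (cfg$model == "mlp") predictExpression(model, X)
        else predictExpression(model, X, lambdaChoice = cfg$lambdaChoice)
    }
    if (length(models) == 1L) return(predictOne(models[[1L]], Xc))
    cond <- conditions(groups)[sampleIds(Xc)]
    parts <- lapply(.CONDITIONS, function(cd) {
        keep <- names(cond)[cond == cd]
        exprValues(predictOne(models[[cd]], .subsetSamples(Xc, keep)))
    })
    out <- do.call(cbind, parts)[, sampleIds(Xc), drop = FALSE]
    ExpressionMatrix(out, scaleTag = "compressed")
}

.subsetSamples <- function(X, ids) {
    ExpressionMatrix(exprValues(X)[, ids, drop = FALSE],
                     scaleTag = scaleTag(X))
}

.writeArtifacts <- function(cfg, report, dea, log) {
    dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
    echo <- cfg
    echo$mlp <- unclass(echo$mlp)
    echo$augment <- if (is.null(echo$augment)) NULL else unclass(echo$augment)
    jsonlite::write_json(unclass(echo),
                         file.path(cfg$outputDir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeConcordanceReport(report, file.path(cfg$outputDir, "report.json"))
    writeDEATable(dea$true, file.path(cfg$outputDir, "dea_true.tsv"))
    writeDEATable(dea$pred, file.path(cfg$outputDir, "dea_pred.tsv"))
    writeScatterData(dea$true, dea$pred,
                     file.path(cfg$outputDir, "scatter_logfc.tsv"))
    writeLines(log$lines(), file.path(cfg$outputDir, "run.log"))
}

#' Within-data evaluation run
#'
#' Trains the configured model on a paired dataset and evaluates it on the
#' same data: preprocess (optional filter, [0,1] compression), optional
#' Gaussian augmentation, model training (joint or one model per
#' condition), prediction on the original (non-augmented) samples, DEA on
#' the true and predicted miRNA matrices, and the concordance report.
#'
#' @param mrna,mirna paired \linkS4class{ExpressionMatrix} objects
#'   (log-intensity scale) sharing samples.
#' @param groups \linkS4class{SampleGroups}.
#' @param cfg a \code{\link{runConfig}} with \code{mode = "within"}.
#' @return list: \code{report} (\linkS4class{ConcordanceReport}),
#'   \code{deaTrue}, \code{deaPred}, \code{predicted}, \code{models},
#'   \code{log}.
#' @examples
#' sim <- simulatePairedDataset(simConfig(nMirna = 30, nMrna = 150, seed = 3))
#' cfg <- runConfig(model = "lasso", conditionHandling = "separate",
#'                  augment = NULL, nlambda = 20, seed = 3)
#' res <- runWithin(sim$mrna, sim$mirna, sim$groups, cfg)
#' res$report
#' @export
runWithin <- function(mrna, mirna, groups, cfg = runConfig()) {
    stopifnot(inherits(cfg, "runConfig"))
    if (!identical(sampleIds(mrna), sampleIds(mirna)))
        stop("mRNA and miRNA matrices must share sample IDs in order")
    .checkGroups(mrna, groups)
    lg <- .makeLog(cfg$verbose)
    lg$log("within-data run: ", cfg$model, ", ", cfg$conditionHandling,
           ", augmentation ", if (is.null(cfg$augment)) "off" else "on",
           ", seed ", cfg$seed)
    px <- .prepMatrix(mrna, cfg, lg$log, "mrna")
    py <- .prepMatrix(mirna, cfg, lg$log, "mirna")
    Xc <- px$X; Yc <- py$X
    trGroups <- groups; Xtr <- Xc; Ytr <- Yc
    if (!is.null(cfg$augment)) {
        aug <- cfg$augment
        aug$seed <- cfg$seed + 100L
        a <- augmentGaussian(Xc, Yc, groups, aug)
        Xtr <- a$X; Ytr <- a$Y; trGroups <- a$groups
        lg$log("augmented to ", length(sampleIds(Xtr)), " samples (seed ",
               aug$seed, ")")
    }
    models <- .trainModels(Xtr, Ytr, trGroups, cfg, lg$log)
    pred <- .predictSamples(models, Xc, groups, cfg)
    dea <- runDEAPair(Yc, pred, groups)
    conc <- deaConcordance(dea$true, dea$pred)
    report <- .concordanceReport(
        samplewiseCorrelation(Yc, pred), conc,
        list(mode = "within", model = cfg$model,
             condition_handling = cfg$conditionHandling,
             augmented = !is.null(cfg$augment),
             filtered = cfg$filterEnabled,
             lambda_choice = if (cfg$model == "lasso") cfg$lambdaChoice else NULL,
             seed = cfg$seed))
    lg$log(sprintf("median sample r = %.3f, r(logFC) = %.3f, r(p) = %.3f",
                   report@medianSampleR, report@rLogFC, report@rPValue))
    if (!is.null(cfg$outputDir)) .writeArtifacts(cfg, report, dea, lg)
    list(report = report, deaTrue = dea$true, deaPred = dea$pred,
         predicted = pred, models = models, log = lg$lines())
}

#' Cross-study evaluation run
#'
#' Trains on one paired dataset and predicts the miRNA profiles of an
#' independent one: feature spaces are intersected (case-insensitive ID
#' match), compression parameters fitted on the training matrices are
#' re-used on the test matrices (with clipping), the model is trained on
#' the (optionally augmented) training study and evaluated against the test
#' study's true miRNA data. With separate condition handling, each test
#' sample is predicted by the model matching its own condition label.
#'
#' @param trainMrna,trainMirna,trainGroups the training study.
#' @param testMrna,testMirna,testGroups the test study.
#' @param cfg a \code{\link{runConfig}}.
#' @return as \code{\link{runWithin}}.
#' @export
runCrossStudy <- function(trainMrna, trainMirna, trainGroups,
                          testMrna, testMirna, testGroups,
                          cfg = runConfig(mode = "cross_study")) {
    stopifnot(inherits(cfg, "runConfig"))
    lg <- .makeLog(cfg$verbose)
    lg$log("cross-study run: ", cfg$model, ", ", cfg$conditionHandling,
           ", augmentation ", if (is.null(cfg$augment)) "off" else "on",
           ", seed ", cfg$seed)
    if (cfg$filterEnabled) {
        trainMrna <- filterLowExpressed(trainMrna, cfg$filterFraction)
        trainMirna <- filterLowExpressed(trainMirna, cfg$filterFraction)
        lg$log("training matrices filtered to ",
               length(featureIds(trainMrna)), " mRNAs / ",
               length(featureIds(trainMirna)), " miRNAs")
    }
    alx <- alignFeatureSpaces(trainMrna, testMrna)
    aly <- alignFeatureSpaces(trainMirna, testMirna)
    lg$log(length(featureIds(alx$train)), " shared mRNAs, ",
           length(featureIds(aly$train)), " shared miRNAs")
    paramsX <- fitCompression(alx$train, "train_mrna",
                              perFeature = cfg$compressPerFeature)
    paramsY <- fitCompression(aly$train, "train_mirna",
                              perFeature = cfg$compressPerFeature)
    XcTr <- applyCompression(alx$train, paramsX)
    YcTr <- applyCompression(aly$train, paramsY)
    XcTe <- applyCompression(alx$test, paramsX)
    YcTe <- applyCompression(aly$test, paramsY)
    trG <- trainGroups; Xtr <- XcTr; Ytr <- YcTr
    if (!is.null(cfg$augment)) {
        aug <- cfg$augment
        aug$seed <- cfg$seed + 100L
        a <- augmentGaussian(XcTr, YcTr, trainGroups, aug)
        Xtr <- a$X; Ytr <- a$Y; trG <- a$groups
        lg$log("training study augmented to ", length(sampleIds(Xtr)),
               " samples")
    }
    models <- .trainModels(Xtr, Ytr, trG, cfg, lg$log)
    pred <- .predictSamples(models, XcTe, testGroups, cfg)
    dea <- runDEAPair(YcTe, pred, testGroups)
    conc <- deaConcordance(dea$true, dea$pred)
    report <- .concordanceReport(
        samplewiseCorrelation(YcTe, pred), conc,
        list(mode = "cross_study", model = cfg$model,
             condition_handling = cfg$conditionHandling,
             augmented = !is.null(cfg$augment),
             filtered = cfg$filterEnabled,
             lambda_choice = if (cfg$model == "lasso") cfg$lambdaChoice else NULL,
             seed = cfg$seed))
    lg$log(sprintf("median sample r = %.3f, r(logFC) = %.3f, r(p) = %.3f",
                   report@medianSampleR, report@rLogFC, report@rPValue))
    if (!is.null(cfg$outputDir)) .writeArtifacts(cfg, report, dea, lg)
    list(report = report, deaTrue = dea$true, deaPred = dea$pred,
         predicted = pred, models = models, log = lg$lines())
}

#' Compare augmentation and condition-handling settings
#'
#' Runs the within-data pipeline over the 2 x 2 grid of (augmentation
#' on/off) x (joint/separate condition handling) and tabulates the
#' concordance metrics, with the log2FC-correlation difference against the
#' non-augmented joint baseline.
#'
#' @param mrna,mirna,groups the paired dataset.
#' @param cfg base \code{\link{runConfig}}; its \code{augment} settings are
#'   used for the augmented rows.
#' @return data.frame with one row per setting: \code{augmented},
#'   \code{condition_handling}, \code{median_sample_r}, \code{r_logfc},
#'   \code{r_pvalue}, \code{delta_r_logfc}.
#' @export
compareSettings <- function(mrna, mirna, groups, cfg = runConfig()) {
    grid <- expand.grid(augmented = c(FALSE, TRUE),
                        condition_handling = c("joint", "separate"),
                        stringsAsFactors = FALSE)
    augCfg <- if (is.null(cfg$augment)) augmentConfig() else cfg$augment
    rows <- lapply(seq_len(nrow(grid)), function(i) {
        ci <- cfg
        ci$augment <- if (grid$augmented[i]) augCfg else NULL
        ci$conditionHandling <- grid$condition_handling[i]
        ci$outputDir <- NULL
        if (ci$model == "lasso" && ci$conditionHandling == "joint")
            ci$allowJointLasso <- TRUE
        res <- runWithin(mrna, mirna, groups, ci)
        data.frame(augmented = grid$augmented[i],
                   condition_handling = grid$condition_handling[i],
                   median_sample_r = res$report@medianSampleR,
                   r_logfc = res$report@rLogFC,
                   r_pvalue = res$report@rPValue)
    })
    out <- do.call(rbind, rows)
    base <- out$r_logfc[!out$augmented & out$condition_handling == "joint"]
    out$delta_r_logfc <- out$r_logfc - base
    out
}
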