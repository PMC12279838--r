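#' Configuration for Gaussian-noise data augmentation
#'
#' Noise is added on the compressed [0,1] scale, where a fixed standard
#' deviation is meaningful across datasets. Augmentation repeats
#' whole-cohort noisy copies until each condition group (or the whole
#' cohort, if \code{perGroup = FALSE}) holds at least \code{minSamples}
#' samples; the original samples are kept.
#'
#' @param noiseSd standard deviation of the i.i.d. Gaussian noise (default
#'   0.01 on the compressed scale).
#' @param minSamples target minimum group size (default 100).
#' @param perGroup interpret \code{minSamples} per condition group
#'   (default) rather than for the whole cohort.
#' @param seed integer seed fully determining the noise.
#' @return validated list of class \code{augmentConfig}.
#' @export
augmentConfig <- function(noiseSd = 0.01, minSamples = 100L, perGroup = TRUE,
                          seed = 1L) {
    stopifnot(noiseSd > 0, minSamples >= 1)
    structure(list(noiseSd = noiseSd, minSamples = as.integer(minSamples),
                   perGroup = isTRUE(perGroup), seed = as.integer(seed)),
              class = "augmentConfig")
}

#' Augment paired expression matrices with Gaussian noise
#'
#' Appends noise-perturbed copies of the cohort to both the predictor (mRNA)
#' and response (miRNA) matrices until the size target of \code{cfg} is met.
#' Paired samples receive independent noise in X and Y but stay paired under
#' a shared new sample ID; condition labels propagate. Values pushed outside
#' [0,1] by the (tiny) noise are left as-is. The RNG is fully determined by
#' \code{cfg$seed} and the caller's RNG state is left untouched.
#'
#' @param X,Y paired \linkS4class{ExpressionMatrix} objects sharing sample
#'   IDs and order (typically compressed mRNA and miRNA).
#' @param groups \linkS4class{SampleGroups} covering the samples.
#' @param cfg an \code{\link{augmentConfig}}.
#' @return list with augmented \code{X}, \code{Y} and \code{groups}.
#' @examples
#' sim <- simulatePairedDataset(simConfig(nMirna = 10, nMrna = 20, seed = 1))
#' aug <- augmentGaussian(sim$mrna, sim$mirna, sim$groups, augmentConfig(seed = 1))
#' table(conditions(aug$groups))
#' @export
augmentGaussian <- function(X, Y, groups, cfg = augmentConfig()) {
    stopifnot(inherits(cfg, "augmentConfig"))
    if (!identical(sampleIds(X), sampleIds(Y)))
        stop("X and Y must share sample IDs in the same order")
    cond <- .checkGroups(X, groups, requireBoth = FALSE)
    sizes <- table(cond)
    if (any(sizes == 0L)) stop("empty condition group; cannot augment")
    # rounds of whole-cohort copies needed so every unit reaches minSamples
    need <- if (cfg$perGroup) max(ceiling(cfg$minSamples / as.vector(sizes)))
            else ceiling(cfg$minSamples / length(cond))
    rounds <- max(0L, as.integer(need) - 1L)
    if (rounds == 0L) return(list(X = X, Y = Y, groups = groups))
    vx <- exprValues(X); vy <- exprValues(Y)
    n <- ncol(vx)
    withr::with_seed(cfg$seed, {
        nx <- matrix(rnorm(length(vx) * rounds, sd = cfg$noiseSd), nrow(vx))
        ny <- matrix(rnorm(length(vy) * rounds, sd = cfg$noiseSd), nrow(vy))
    })
    newX <- do.call(cbind, lapply(seq_len(rounds), function(r)
        vx + nx[, (r - 1L) * n + seq_len(n), drop = FALSE]))
    newY <- do.call(cbind, lapply(seq_len(rounds), function(r)
        vy + ny[, (r - 1L) * n + seq_len(n), drop = FALSE]))
    ids <- as.vector(vapply(seq_len(rounds), function(r)
        paste0(colnames(vx), "_aug", r), character(n)))
    colnames(newX) <- colnames(newY) <- ids
    allX <- cbind(vx, newX); allY <- cbind(vy, newY)
    allCond <- setNames(rep(as.character(cond), rounds + 1L), colnames(allX))
    list(X = ExpressionMatrix(allX, scaleTag = scaleTag(X)),
         Y = ExpressionMatrix(allY, scaleTag = scaleTag(Y)),
         groups = SampleGroups(allCond))
}
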