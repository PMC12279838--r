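#' Configuration for the paired mRNA/miRNA simulator
#'
#' The simulator emulates a small two-group paired transcriptome study on
#' the log-intensity scale: each miRNA has a baseline level, a subset is
#' differentially expressed in the diseased group (shift \code{deEffect}
#' with random sign), and every miRNA represses a fixed-size random target
#' set of mRNAs in proportion to its centered expression. Defaults mirror a
#' 5-versus-5 microarray design with a few hundred miRNAs, a few thousand
#' mRNAs and moderate measurement noise.
#'
#' @param nMirna,nMrna numbers of miRNA and mRNA features.
#' @param nControl,nDiseased samples per condition.
#' @param targetsPerMirna size of every miRNA's mRNA target set (sets may
#'   overlap).
#' @param repressionStrength regression coefficient beta of mRNA on each
#'   targeting miRNA's centered level (positive value acts as repression).
#' @param fracDeMirna fraction of miRNAs differentially expressed.
#' @param deEffect absolute log-scale group shift delta of DE miRNAs.
#' @param noiseSdMrna,noiseSdMirna residual log-scale noise.
#' @param baselineRange uniform range of per-feature baseline log
#'   intensities.
#' @param seed integer seed; the draw is bit-reproducible.
#' @return validated list of class \code{simConfig}.
#' @export
simConfig <- function(nMirna = 300L, nMrna = 2000L, nControl = 5L,
                      nDiseased = 5L, targetsPerMirna = 20L,
                      repressionStrength = 0.4, fracDeMirna = 0.2,
                      deEffect = 1.0, noiseSdMrna = 0.3, noiseSdMirna = 0.2,
                      baselineRange = c(4, 12), seed = 1L) {
    stopifnot(nMirna >= 1, nMrna >= 1, nControl >= 1, nDiseased >= 1,
              targetsPerMirna >= 1, targetsPerMirna <= nMrna,
              fracDeMirna >= 0, fracDeMirna <= 1,
              noiseSdMrna > 0, noiseSdMirna > 0,
              length(baselineRange) == 2, baselineRange[2] > baselineRange[1])
    structure(list(nMirna = as.integer(nMirna), nMrna = as.integer(nMrna),
                   nControl = as.integer(nControl),
                   nDiseased = as.integer(nDiseased),
                   targetsPerMirna = as.integer(targetsPerMirna),
                   repressionStrength = repressionStrength,
                   fracDeMirna = fracDeMirna, deEffect = deEffect,
                   noiseSdMrna = noiseSdMrna, noiseSdMirna = noiseSdMirna,
                   baselineRange = baselineRange, seed = as.integer(seed)),
              class = "simConfig")
}

# draw the study structure: baselines, target map, DE set and signs
.simStructure <- function(cfg) {
    mirnaIds <- sprintf("mir%03d", seq_len(cfg$nMirna))
    mrnaIds <- sprintf("gene%04d", seq_len(cfg$nMrna))
    mu <- runif(cfg$nMirna, cfg$baselineRange[1], cfg$baselineRange[2])
    b <- runif(cfg$nMrna, cfg$baselineRange[1], cfg$baselineRange[2])
    targetMap <- lapply(seq_len(cfg$nMirna), function(g)
        sample.int(cfg$nMrna, cfg$targetsPerMirna))
    names(targetMap) <- mirnaIds
    nDe <- round(cfg$fracDeMirna * cfg$nMirna)
    deIdx <- if (nDe > 0) sort(sample.int(cfg$nMirna, nDe)) else integer()
    sign <- setNames(sample(c(-1, 1), nDe, replace = TRUE), mirnaIds[deIdx])
    logfc <- setNames(numeric(cfg$nMirna), mirnaIds)
    logfc[mirnaIds[deIdx]] <- cfg$deEffect * sign
    new("SimTruth", targetMap = targetMap, deMirnaIds = mirnaIds[deIdx],
        deSign = sign, trueMirnaLogFC = logfc,
        mirnaBaseline = setNames(mu, mirnaIds),
        mrnaBaseline = setNames(b, mrnaIds))
}

#' Simulate a paired mRNA/miRNA two-group dataset
#'
#' Generates log-intensity matrices for both omics layers with a known
#' miRNA-to-target repression structure:
#' \deqn{miRNA_{gs} = \mu_g + \delta \, sign_g \, [g \in DE][s \in diseased]
#'   + \varepsilon,\quad \varepsilon \sim N(0, \sigma_{miRNA}^2)}
#' \deqn{mRNA_{ms} = b_m - \beta \sum_{g: m \in targets(g)}
#'   (miRNA_{gs} - \mu_g) + \eta,\quad \eta \sim N(0, \sigma_{mRNA}^2)}
#' Repression acts on the centered miRNA values so baselines do not shift
#' mRNA means. Passing a \code{truth} reuses an existing study structure
#' (baselines, target map, DE set) and only redraws samples — the
#' "independent study of the same disease" scenario used by cross-study
#' evaluations.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param truth optional \linkS4class{SimTruth} to reuse.
#' @return list with \code{mrna}, \code{mirna}
#'   (\linkS4class{ExpressionMatrix}, log-intensity scale), \code{groups}
#'   (\linkS4class{SampleGroups}) and \code{truth}
#'   (\linkS4class{SimTruth}).
#' @examples
#' sim <- simulatePairedDataset(simConfig(nMirna = 20, nMrna = 100, seed = 7))
#' sim$mirna
#' @export
simulatePairedDataset <- function(cfg = simConfig(), truth = NULL) {
    stopifnot(inherits(cfg, "simConfig"))
    if (!is.null(truth))
        stopifnot(length(truth@mirnaBaseline) == cfg$nMirna,
                  length(truth@mrnaBaseline) == cfg$nMrna)
    withr::with_seed(cfg$seed, {
        if (is.null(truth)) truth <- .simStructure(cfg)
        ns <- cfg$nControl + cfg$nDiseased
        sampleIds <- c(sprintf("ctl%02d", seq_len(cfg$nControl)),
                       sprintf("dis%02d", seq_len(cfg$nDiseased)))
        diseased <- rep(c(FALSE, TRUE), c(cfg$nControl, cfg$nDiseased))
        mu <- truth@mirnaBaseline
        shift <- truth@trueMirnaLogFC %o% as.numeric(diseased)
        mirna <- mu + shift +
            matrix(rnorm(cfg$nMirna * ns, sd = cfg$noiseSdMirna),
                   cfg$nMirna, ns)
        # repression: accumulate each miRNA's centered level into its targets
        centered <- mirna - mu
        load <- matrix(0, cfg$nMrna, ns)
        for (g in seq_len(cfg$nMirna)) {
            tg <- truth@targetMap[[g]]
            load[tg, ] <- load[tg, ] + rep(centered[g, ], each = length(tg))
        }
        mrna <- truth@mrnaBaseline - cfg$repressionStrength * load +
            matrix(rnorm(cfg$nMrna * ns, sd = cfg$noiseSdMrna), cfg$nMrna, ns)
        dimnames(mirna) <- list(names(truth@mirnaBaseline), sampleIds)
        dimnames(mrna) <- list(names(truth@mrnaBaseline), sampleIds)
        groups <- SampleGroups(setNames(
            ifelse(diseased, "diseased", "control"), sampleIds))
        list(mrna = ExpressionMatrix(mrna, "log_intensity"),
             mirna = ExpressionMatrix(mirna, "log_intensity"),
             groups = groups, truth = truth)
    })
}

#' Expected miRNA log fold changes of a simulated dataset
#'
#' The oracle against which empirical fold changes are checked:
#' \code{deEffect * sign} for DE miRNAs and 0 otherwise.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @return named numeric vector over miRNAs.
#' @export
expectedMirnaLogFC <- function(truth) truth@trueMirnaLogFC

#' Write a simulated dataset in the package's standard file formats
#'
#' Emits the mRNA and miRNA matrices as TSV, the sample sheet, and the
#' simulation truth (DE table and target map) as TSV files.
#'
#' @param sim result of \code{\link{simulatePairedDataset}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulatedDataset <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeExpressionMatrix(sim$mrna, file.path(dir, "mrna.tsv"))
    writeExpressionMatrix(sim$mirna, file.path(dir, "mirna.tsv"))
    writeSampleGroups(sim$groups, file.path(dir, "samples.tsv"))
    write.table(data.frame(mirna = names(sim$truth@trueMirnaLogFC),
                           true_logfc = sim$truth@trueMirnaLogFC,
                           is_de = names(sim$truth@trueMirnaLogFC) %in%
                               sim$truth@deMirnaIds),
                file.path(dir, "truth_mirna.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tm <- sim$truth@targetMap
    write.table(data.frame(mirna = rep(names(tm), lengths(tm)),
                           target_index = unlist(tm)),
                file.path(dir, "truth_targets.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}
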