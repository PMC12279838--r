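#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV expression matrix whose first column holds feature IDs and
#' whose header row holds sample IDs. Duplicate feature IDs are collapsed by
#' the mean of their rows (reported via a message); rows containing
#' non-finite values are dropped by the \code{\link{ExpressionMatrix}}
#' constructor.
#'
#' @param path file path.
#' @param delimiter field delimiter, default tab.
#' @param scaleTag declared scale of the stored values.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readExpressionMatrix <- function(path, delimiter = "\t",
                                 scaleTag = "log_intensity") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, sep = delimiter, header = TRUE,
                     check.names = FALSE, stringsAsFactors = FALSE,
                     colClasses = "character")
    if (ncol(df) < 2L) stop("malformed header in ", path,
                            ": need a feature-ID column plus >=1 sample column")
    ids <- df[[1L]]
    vals <- as.matrix(df[, -1L, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                   dimnames = dimnames(vals)))
    # cells that are empty/NA/NaN markers become non-finite and their rows
    # are dropped below; anything else non-numeric is a parse error
    missingCell <- is.na(vals) |
        matrix(toupper(vals) %in% c("NA", "NAN", ""), nrow = nrow(vals))
    bad <- which(is.na(num) & !missingCell, arr.ind = TRUE)
    if (nrow(bad)) {
        stop(sprintf("non-numeric cell in %s at row %d, column %d (value '%s')",
                     path, bad[1, 1] + 1L, bad[1, 2] + 1L,
                     vals[bad[1, 1], bad[1, 2]]))
    }
    if (nrow(num) == 0L) stop("empty matrix in ", path)
    # literal NA/NaN strings become NaN so the constructor drops those rows
    num[is.na(num)] <- NaN
    if (anyDuplicated(ids)) {
        ndup <- sum(duplicated(ids))
        message(ndup, " duplicate feature ID row(s) collapsed by mean")
        num <- rowsum(num, group = ids, reorder = FALSE) /
            as.vector(table(factor(ids, levels = unique(ids))))
        ids <- unique(ids)
    }
    rownames(num) <- ids
    ExpressionMatrix(num, scaleTag = scaleTag)
}

#' Write an expression matrix to a delimited file
#'
#' Inverse of \code{\link{readExpressionMatrix}}: first column
#' \code{feature_id}, one column per sample. Values survive a round trip to
#' at least 1e-9.
#'
#' @param X an \linkS4class{ExpressionMatrix}.
#' @param path output file path.
#' @param delimiter field delimiter.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(X, path, delimiter = "\t") {
    df <- data.frame(feature_id = featureIds(X), exprValues(X),
                     check.names = FALSE)
    write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                path, sep = delimiter, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a sample sheet into SampleGroups
#'
#' Two-column delimited file: sample ID, condition (\code{control} or
#' \code{diseased}). Any other label is rejected with the allowed labels
#' named.
#'
#' @param path file path.
#' @param delimiter field delimiter.
#' @return A \linkS4class{SampleGroups}.
#' @export
readSampleGroups <- function(path, delimiter = "\t") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, sep = delimiter, header = TRUE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("sample sheet needs two columns: sample_id, condition")
    SampleGroups(setNames(as.character(df[[2L]]), as.character(df[[1L]])))
}

#' Write a SampleGroups sample sheet
#' @param groups a \linkS4class{SampleGroups}.
#' @param path output path.
#' @param delimiter field delimiter.
#' @return \code{path}, invisibly.
#' @export
writeSampleGroups <- function(groups, path, delimiter = "\t") {
    write.table(data.frame(sample_id = sampleIds(groups),
                           condition = as.character(conditions(groups))),
                path, sep = delimiter, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a transcription-factor list
#'
#' Plain text, one gene symbol per line; blank lines ignored. Matching
#' against expression features is case-insensitive downstream.
#'
#' @param path file path.
#' @return character vector of unique TF symbols.
#' @export
readTFList <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    x <- trimws(readLines(path, warn = FALSE))
    unique(x[nzchar(x)])
}

#' Restrict two expression matrices to their shared feature space
#'
#' Cross-study runs require train and test matrices over identical features.
#' Features are matched by case-insensitive exact string comparison of their
#' IDs (no probe-to-gene translation); both outputs are restricted to the
#' intersection in a common order (the training matrix's feature order).
#'
#' @param train,test \linkS4class{ExpressionMatrix} objects.
#' @return list with elements \code{train} and \code{test}, row-aligned.
#' @export
alignFeatureSpaces <- function(train, test) {
    keyTr <- toupper(featureIds(train))
    keyTe <- toupper(featureIds(test))
    common <- intersect(keyTr, keyTe)
    if (length(common) == 0L)
        stop("no shared features between the two matrices; ",
             "harmonize feature identifiers (e.g., map probes to gene symbols) first")
    message(length(common), " shared features retained")
    iTr <- match(common, keyTr)
    iTe <- match(common, keyTe)
    ord <- order(iTr)   # keep training matrix's original row order
    iTr <- iTr[ord]; iTe <- iTe[ord]
    list(train = ExpressionMatrix(exprValues(train)[iTr, , drop = FALSE],
                                  scaleTag = scaleTag(train)),
         test = ExpressionMatrix(exprValues(test)[iTe, , drop = FALSE],
                                 scaleTag = scaleTag(test)))
}

# internal: check that groups cover exactly the samples of X, >=2 per group
.checkGroups <- function(X, groups, requireBoth = TRUE) {
    cond <- conditions(groups)
    missing <- setdiff(sampleIds(X), names(cond))
    if (length(missing))
        stop("sample(s) missing from the sample sheet: ",
             paste(missing, collapse = ", "))
    cond <- cond[sampleIds(X)]
    if (requireBoth && any(table(cond) < 2L))
        stop("both conditions need >=2 samples for differential expression")
    cond
}
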