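# Plain-text readers and writers for the pipeline's inputs and artifacts.

#' Read a gene x timed-sample count matrix
#'
#' Expects a TSV/CSV with gene identifiers in the first column and one column
#' per sample, headers encoding the sampling time in minutes either as bare
#' numbers or as \code{t}-prefixed zero-padded ids (e.g. \code{t0004}).
#'
#' @param path file path.
#' @param sep field separator (tab by default; use "," for CSV).
#' @param interval nominal grid interval; inferred from the times when
#'   \code{NULL}.
#' @return A \linkS4class{TimeCourseExperiment}.
#' @export
readCountMatrix <- function(path, sep = "\t", interval = NULL) {
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            row.names = 1L, check.names = FALSE)
    times <- suppressWarnings(as.numeric(sub("^t", "", colnames(df))))
    if (anyNA(times))
        stop("column headers must encode sampling times (e.g. 't0004' or '4')")
    m <- as.matrix(df)[, order(times), drop = FALSE]
    TimeCourseExperiment(m, .timeGridFromTimes(sort(times), interval))
}

#' Write a count matrix as TSV
#'
#' @param tce a \linkS4class{TimeCourseExperiment}.
#' @param path output path.
#' @param assayName assay to write (default \code{"counts"}).
#' @export
writeCountMatrix <- function(tce, path, assayName = "counts") {
    m <- assay(tce, assayName)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a newline-delimited gene list
#'
#' @param path file path.
#' @return Character vector (empty lines removed).
#' @export
readGeneList <- function(path) {
    x <- readLines(path)
    x[nzchar(trimws(x))]
}

#' Write a two-column table of per-sample size factors
#'
#' @param tce a normalized \linkS4class{TimeCourseExperiment}.
#' @param path output path.
#' @export
writeSizeFactors <- function(tce, path) {
    utils::write.table(
        data.frame(sample = colnames(tce),
                   factor = colData(tce)$sizeFactor),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write simulation ground truth as TSV
#'
#' @param tce a simulated \linkS4class{TimeCourseExperiment}.
#' @param path output path.
#' @export
writeGroundTruth <- function(tce, path) {
    gt <- groundTruth(tce)
    if (is.null(gt)) stop("experiment carries no ground truth")
    utils::write.table(gt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
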