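#' Remove listed genes from a count matrix
#'
#' Drops rows whose identifier is in \code{exclude} (e.g. a user-supplied
#' mitochondrial gene list) before normalization. Identifiers absent from the
#' matrix are ignored with a message.
#'
#' @param tce a \linkS4class{TimeCourseExperiment}.
#' @param exclude character vector of gene identifiers to remove.
#' @return The experiment without the excluded rows.
#' @export
removeGenes <- function(tce, exclude) {
    exclude <- unique(as.character(exclude))
    if (length(exclude) == 0L) return(tce)
    hit <- rownames(tce) %in% exclude
    missing <- setdiff(exclude, rownames(tce))
    if (length(missing))
        message(sprintf("removeGenes: %d excluded ids not present (ignored)",
                        length(missing)))
    tce[!hit, ]
}

#' Sum technical-replicate lanes per time point
#'
#' Samples sequenced across several lanes for the same time point are summed
#' into one column before normalization. The lane map assigns each current
#' column to a time; columns sharing a time are added together.
#'
#' @param counts numeric matrix, genes x lanes.
#' @param laneTimes numeric vector of sampling times (minutes), one per
#'   column of \code{counts}.
#' @param interval nominal sampling interval of the resulting grid (inferred
#'   when \code{NULL}).
#' @return A \linkS4class{TimeCourseExperiment} with one column per time.
#' @export
sumLanes <- function(counts, laneTimes, interval = NULL) {
    counts <- as.matrix(counts)
    if (length(laneTimes) != ncol(counts))
        stop("laneTimes must have one entry per column")
    times <- sort(unique(laneTimes))
    summed <- vapply(times,
        function(tt) rowSums(counts[, laneTimes == tt, drop = FALSE]),
        numeric(nrow(counts)))
    rownames(summed) <- rownames(counts)
    TimeCourseExperiment(summed, .timeGridFromTimes(times, interval))
}

# Anders-Huber median-ratio size factors. Reference genes are the rows with
# strictly positive counts in every sample (finite log geometric mean);
# zero-containing genes are normalized but never inform the factors.
.medianRatioSizeFactors <- function(counts) {
    logGeo <- rowMeans(log(counts))
    ref <- is.finite(logGeo)
    if (!any(ref))
        stop(paste("median-ratio normalization needs at least one gene with",
                   "strictly positive counts in every sample"))
    apply(counts, 2L, function(col) {
        exp(stats::median((log(col) - logGeo)[ref]))
    })
}

#' Median-ratio normalization
#'
#' Computes per-sample size factors as the median, over reference genes, of
#' the ratio of a sample's count to the gene's geometric mean across samples,
#' then divides each column by its factor. Only genes with strictly positive
#' counts in every sample act as references; all genes are returned
#' normalized. Factors are stored in \code{colData(tce)$sizeFactor} and the
#' \code{"normalized"} assay is added.
#'
#' @param tce a \linkS4class{TimeCourseExperiment} with a \code{counts} assay.
#' @return The experiment with a \code{normalized} assay and size factors.
#' @examples
#' g <- makeTimeGrid(10, 30)
#' m <- matrix(c(10, 20, 10, 20, 10, 20, 10, 20),
#'             2, 4, dimnames = list(c("a", "b"), NULL))
#' colData(medianRatioNormalize(TimeCourseExperiment(m, g)))$sizeFactor
#' @export
medianRatioNormalize <- function(tce) {
    if (nrow(tce) == 0L)
        .stageError("normalize", "count matrix has no genes")
    counts <- assay(tce, "counts")
    sf <- .medianRatioSizeFactors(counts)
    assay(tce, "normalized") <- sweep(counts, 2L, sf, "/")
    colData(tce)$sizeFactor <- sf
    metadata(tce)$provenance <- c(metadata(tce)$provenance,
                                  "median-ratio normalization")
    tce
}

#' Drop genes below a mean-expression floor
#'
#' Removes genes whose average normalized expression across all samples is
#' strictly smaller than \code{threshold} (a mean of exactly
#' \code{threshold} is retained).
#'
#' @param tce a normalized \linkS4class{TimeCourseExperiment}.
#' @param threshold mean normalized-count floor (default 10).
#' @return The filtered experiment; the number of dropped genes is reported
#'   via \code{message}.
#' @export
filterLowExpression <- function(tce, threshold = 10) {
    if (!"normalized" %in% assayNames(tce))
        .stageError("filter", "normalize before filtering (no 'normalized' assay)")
    keep <- rowMeans(assay(tce, "normalized")) >= threshold
    message(sprintf("filterLowExpression: dropped %d / %d genes with mean < %g",
                    sum(!keep), length(keep), threshold))
    tce[keep, ]
}

#' Scale each gene to the unit interval
#'
#' Maps every retained gene's normalized profile to
#' \code{(y - min(y)) / (max(y) - min(y))} so that each row attains 0 and 1
#' exactly and slopes are comparable across genes and species. Genes with
#' zero dynamic range (constant profiles) are dropped with a message.
#'
#' @param tce a normalized \linkS4class{TimeCourseExperiment}.
#' @return The experiment restricted to scalable genes, with a
#'   \code{"scaled"} assay whose rows lie in \[0, 1\].
#' @export
scaleUnitInterval <- function(tce) {
    src <- if ("normalized" %in% assayNames(tce)) "normalized" else "counts"
    y <- assay(tce, src)
    rng <- apply(y, 1L, function(r) diff(range(r)))
    flat <- rng <= 0
    if (any(flat))
        message(sprintf(
            "scaleUnitInterval: dropped %d genes with zero dynamic range",
            sum(flat)))
    if (all(flat))
        .stageError("scale", "no gene has a nonzero dynamic range")
    tce <- tce[!flat, ]
    y <- assay(tce, src)
    lo <- apply(y, 1L, min)
    hi <- apply(y, 1L, max)
    assay(tce, "scaled") <- (y - lo) / (hi - lo)
    metadata(tce)$provenance <- c(metadata(tce)$provenance,
                                  "unit-interval scaling")
    tce
}
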