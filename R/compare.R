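# Cross-species / cross-condition kinetic statistics.

#' Load a two-column ortholog table and enforce 1:1 pairs
#'
#' Reads a two-column TSV (species-A id, species-B id), collapses duplicated
#' rows, and removes every pair involved in a many-to-many mapping so that
#' each identifier appears in at most one retained pair (paired tests stay
#' well-defined). Removals are reported with a message.
#'
#' @param path path to the TSV (header optional, detected by column content).
#' @return \code{data.frame} with columns \code{geneA}, \code{geneB}.
#' @export
loadOrthologMap <- function(path) {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("geneA", "geneB"))
    if (nrow(raw) && raw$geneA[1L] %in% c("geneA", "gene_a", "speciesA"))
        raw <- raw[-1L, , drop = FALSE]
    orthologMap(raw)
}

#' @rdname loadOrthologMap
#' @param pairs \code{data.frame} whose first two columns are the paired ids.
#' @export
orthologMap <- function(pairs) {
    pairs <- unique(data.frame(geneA = as.character(pairs[[1L]]),
                               geneB = as.character(pairs[[2L]]),
                               stringsAsFactors = FALSE))
    if (nrow(pairs) == 0L) stop("no ortholog pairs")
    ambig <- pairs$geneA %in% pairs$geneA[duplicated(pairs$geneA)] |
             pairs$geneB %in% pairs$geneB[duplicated(pairs$geneB)]
    if (any(ambig))
        message(sprintf("orthologMap: removed %d many-to-many pairs",
                        sum(ambig)))
    out <- pairs[!ambig, , drop = FALSE]
    if (nrow(out) == 0L) stop("no ortholog pairs")
    rownames(out) <- NULL
    out
}

#' Shift in event-time distributions (Hodges-Lehmann / Wilcoxon)
#'
#' Estimates how much later events (breakpoints or peaks) occur in group B
#' than in group A as the Hodges-Lehmann shift of \code{timesB} relative to
#' \code{timesA}, with a Wilcoxon-based confidence interval
#' (\code{stats::wilcox.test} with \code{conf.int = TRUE}; the paired variant
#' uses signed within-pair differences in ortholog order). Positive values
#' mean group A is earlier.
#'
#' @param timesA,timesB numeric event times (minutes); for \code{paired}
#'   the vectors must align pair-by-pair.
#' @param paired use the paired (signed-rank) variant.
#' @param conf confidence level (default 0.99).
#' @return List of class \code{"ShiftEstimate"}: \code{estimate},
#'   \code{ciLow}, \code{ciHigh}, \code{conf}, \code{paired}, \code{nA},
#'   \code{nB}, \code{degenerate}.
#' @examples
#' deltaM(c(10, 20, 30), c(110, 125, 128))
#' @export
deltaM <- function(timesA, timesB, paired = FALSE, conf = 0.99) {
    timesA <- as.numeric(timesA)
    timesB <- as.numeric(timesB)
    if (length(timesA) < 1L || length(timesB) < 1L)
        stop("both groups need at least one event time")
    if (paired && length(timesA) != length(timesB))
        stop("paired comparison requires equal-length, pair-aligned vectors")
    wt <- tryCatch(
        suppressWarnings(stats::wilcox.test(timesB, timesA, paired = paired,
                                            conf.int = TRUE,
                                            conf.level = conf)),
        error = function(e) NULL)
    degenerate <- is.null(wt) || anyNA(wt$conf.int) ||
        any(!is.finite(wt$conf.int))
    if (degenerate)
        warning("deltaM: degenerate (all-tied) data; CI undefined")
    structure(list(
        estimate = if (is.null(wt)) NA_real_ else unname(wt$estimate),
        ciLow = if (degenerate) NA_real_ else wt$conf.int[1L],
        ciHigh = if (degenerate) NA_real_ else wt$conf.int[2L],
        conf = conf, paired = paired,
        nA = length(timesA), nB = length(timesB),
        degenerate = degenerate), class = "ShiftEstimate")
}

#' Difference in category proportions (percent)
#'
#' Continuity-corrected two-proportion z-test confidence interval on
#' \code{kA/nA - kB/nB}, multiplied by 100 (via \code{stats::prop.test}).
#'
#' @param kA,nA successes and trials in group A.
#' @param kB,nB successes and trials in group B.
#' @param conf confidence level (default 0.99).
#' @return List of class \code{"ProportionDiff"}: \code{estimate} (percent),
#'   \code{ciLow}, \code{ciHigh}, counts and \code{conf}.
#' @examples
#' deltaP(45, 50, 40, 50)
#' @export
deltaP <- function(kA, nA, kB, nB, conf = 0.99) {
    if (nA <= 0 || nB <= 0) stop("group sizes must be positive")
    if (kA < 0 || kA > nA || kB < 0 || kB > nB)
        stop("counts must satisfy 0 <= k <= n")
    pt <- suppressWarnings(stats::prop.test(c(kA, kB), c(nA, nB),
                                            conf.level = conf))
    structure(list(
        estimate = 100 * (kA / nA - kB / nB),
        ciLow = 100 * pt$conf.int[1L], ciHigh = 100 * pt$conf.int[2L],
        kA = kA, nA = nA, kB = kB, nB = nB, conf = conf),
        class = "ProportionDiff")
}

#' Ratio of median slope magnitudes with bootstrap CI
#'
#' \code{median(|slopesA|) / median(|slopesB|)}, a nonparametric measure of
#' how much steeper group A's expression changes are, with a percentile
#' bootstrap confidence interval from independent within-group resampling.
#' Values above 1 mean faster kinetics in group A.
#'
#' @param slopesA,slopesB numeric segment slopes (scaled expression per
#'   minute); magnitudes are compared, so signs are ignored.
#' @param conf confidence level (default 0.99).
#' @param B number of bootstrap resamples (default 10000).
#' @param seed integer seed for the bootstrap.
#' @return List of class \code{"SlopeRatio"}: \code{estimate}, \code{ciLow},
#'   \code{ciHigh}, \code{nA}, \code{nB}, \code{B}, \code{seed}, \code{conf}.
#' @examples
#' deltaS(c(0.02, 0.03, 0.025), c(0.01, 0.012, 0.015), B = 200)
#' @export
deltaS <- function(slopesA, slopesB, conf = 0.99, B = 10000L, seed = 1L) {
    a <- abs(as.numeric(slopesA))
    b <- abs(as.numeric(slopesB))
    if (length(a) == 0L || length(b) == 0L)
        stop("both slope groups must be nonempty")
    if (stats::median(b) == 0)
        stop("median slope magnitude of group B is zero")
    est <- stats::median(a) / stats::median(b)
    ratios <- .withSeed(seed, {
        ma <- matrix(sample(a, length(a) * B, replace = TRUE), ncol = B)
        mb <- matrix(sample(b, length(b) * B, replace = TRUE), ncol = B)
        apply(ma, 2L, stats::median) / apply(mb, 2L, stats::median)
    })
    qs <- stats::quantile(ratios, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
    structure(list(estimate = est, ciLow = qs[1L], ciHigh = qs[2L],
                   nA = length(a), nB = length(b), B = as.integer(B),
                   seed = as.integer(seed), conf = conf),
              class = "SlopeRatio")
}

#' @export
print.ShiftEstimate <- function(x, ...) {
    cat(sprintf("Shift (B - A): %.2f min, %g%% CI [%.2f, %.2f], %s, nA=%d nB=%d\n",
                x$estimate, 100 * x$conf, x$ciLow, x$ciHigh,
                if (x$paired) "paired" else "unpaired", x$nA, x$nB))
    invisible(x)
}

#' @export
print.ProportionDiff <- function(x, ...) {
    cat(sprintf("Proportion difference (A - B): %.2f%%, %g%% CI [%.2f%%, %.2f%%]\n",
                x$estimate, 100 * x$conf, x$ciLow, x$ciHigh))
    invisible(x)
}

#' @export
print.SlopeRatio <- function(x, ...) {
    cat(sprintf("Median |slope| ratio (A / B): %.3f, %g%% CI [%.3f, %.3f]\n",
                x$estimate, 100 * x$conf, x$ciLow, x$ciHigh))
    invisible(x)
}

#' Keep every k-th sample of a time course
#'
#' Emulates a reduced sampling rate (e.g. every 3rd sample of a 4-minute
#' grid gives an effective 12-minute design) for robustness re-analysis.
#'
#' @param tce a \linkS4class{TimeCourseExperiment}.
#' @param k keep every \code{k}-th sample.
#' @param offset zero-based index of the first retained sample.
#' @return The subsampled experiment with an updated grid.
#' @export
subsampleEveryK <- function(tce, k = 3L, offset = 0L) {
    if (k < 1L) stop("k must be at least 1")
    idx <- seq(1L + offset, ncol(tce), by = k)
    if (length(idx) < 2L) stop("fewer than 2 samples would remain")
    tce[, idx]
}

#' Overlap of dynamic genes between two conditions
#'
#' Counts genes dynamic in both fit sets and, among those, splits them by
#' their first non-flat segment direction: same direction in both conditions
#' means "similar", opposite directions "opposite". Breakpoint-time vectors
#' per condition are returned for histogram comparison.
#'
#' @param fitsCondition,fitsControl \linkS4class{TrendFitSet} objects over
#'   comparable gene identifiers.
#' @param gate adjusted R-squared gate (defaults to each set's option).
#' @return List with counts (\code{nCondition}, \code{nControl},
#'   \code{nShared}, \code{nSimilar}, \code{nOpposite}), the shared gene
#'   ids, and per-condition breakpoint time vectors.
#' @export
controlOverlap <- function(fitsCondition, fitsControl, gate = NULL) {
    dynA <- dynamicGenes(fitsCondition, gate)
    dynB <- dynamicGenes(fitsControl, gate)
    shared <- intersect(dynA, dynB)
    if (length(intersect(fitsCondition@geneIds, fitsControl@geneIds)) == 0L)
        stop("the two fit sets share no gene identifiers")
    firstDir <- function(fit) {
        d <- fit@directions[fit@directions != "same"]
        if (length(d)) d[1L] else NA_character_
    }
    simil <- vapply(shared, function(g) {
        a <- firstDir(fitsCondition[[g]])
        b <- firstDir(fitsControl[[g]])
        if (is.na(a) || is.na(b)) NA else a == b
    }, logical(1))
    list(nCondition = length(dynA), nControl = length(dynB),
         nShared = length(shared),
         nSimilar = sum(simil, na.rm = TRUE),
         nOpposite = sum(!simil, na.rm = TRUE),
         sharedGenes = shared,
         breakpointsCondition = unlist(lapply(
             shared, function(g) fitsCondition[[g]]@breakpoints)),
         breakpointsControl = unlist(lapply(
             shared, function(g) fitsControl[[g]]@breakpoints)))
}

#' First-versus-last window change on exon and intron counts
#'
#' Treats the first and last \code{window} time points as two conditions and
#' computes, per gene, the difference in mean normalized expression between
#' them on both the exon and intron tracks, plus the cross-gene Pearson
#' correlation of the two changes (high correlation indicates the intron
#' signal tracks transcriptional activity).
#'
#' @param exonTce,intronTce \linkS4class{TimeCourseExperiment}s with matched
#'   gene ids and grids (normalized assays are used when present).
#' @param window number of time points per window (default 10).
#' @return List with \code{perGene} (gene, exonChange, intronChange) and
#'   \code{correlation}.
#' @export
intronExonChange <- function(exonTce, intronTce, window = 10L) {
    shared <- intersect(rownames(exonTce), rownames(intronTce))
    if (length(shared) == 0L) stop("no shared gene identifiers")
    if (ncol(exonTce) != ncol(intronTce))
        stop("exon and intron experiments must share the time grid")
    if (ncol(exonTce) < 2L * window)
        stop("grid shorter than 2 * window")
    pick <- function(tce) {
        nm <- if ("normalized" %in% assayNames(tce)) "normalized" else "counts"
        assay(tce, nm)[shared, , drop = FALSE]
    }
    change <- function(m) {
        n <- ncol(m)
        rowMeans(m[, (n - window + 1L):n, drop = FALSE]) -
            rowMeans(m[, 1:window, drop = FALSE])
    }
    dEx <- change(pick(exonTce))
    dIn <- change(pick(intronTce))
    list(perGene = data.frame(gene = shared, exonChange = unname(dEx),
                              intronChange = unname(dIn),
                              stringsAsFactors = FALSE),
         correlation = stats::cor(dEx, dIn))
}
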