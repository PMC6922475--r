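# Config-driven orchestration: counts (read or simulated) -> preprocessing ->
# segmented fits -> pattern tables and censuses -> cross-species comparisons.

#' Cross-group kinetic comparison report
#'
#' Computes the package's comparison statistics between two fitted datasets:
#' Hodges-Lehmann shifts of first-breakpoint and first-peak times
#' (\code{deltaM}, positive when group A is earlier), percent differences in
#' immediate-onset and monotonic genes (\code{deltaP}, A minus B), and ratios
#' of median slope magnitudes (\code{deltaS}, above 1 when A is steeper).
#' With an ortholog map, statistics are computed on 1:1 pairs (paired
#' Wilcoxon for event times); they are always also computed over all dynamic
#' genes of each dataset.
#'
#' @param patternsA,patternsB pattern tables from [patternTable()].
#' @param orthologs optional two-column 1:1 map (\code{geneA}, \code{geneB});
#'   see [orthologMap()].
#' @param conf confidence level (default 0.99).
#' @param B bootstrap resamples for the slope-ratio CIs.
#' @param seed integer seed for the bootstrap.
#' @return \code{data.frame} with columns \code{statistic}, \code{scope},
#'   \code{estimate}, \code{ciLow}, \code{ciHigh}, \code{nA}, \code{nB}.
#' @export
compareKinetics <- function(patternsA, patternsB, orthologs = NULL,
                            conf = 0.99, B = 10000L, seed = 1L) {
    rows <- list()
    addRow <- function(statistic, scope, est, lo, hi, nA, nB) {
        rows[[length(rows) + 1L]] <<- data.frame(
            statistic = statistic, scope = scope, estimate = est,
            ciLow = lo, ciHigh = hi, nA = nA, nB = nB,
            stringsAsFactors = FALSE)
    }
    isMono <- function(p) p$label %in% c("monotonic_up", "monotonic_down")
    statBlock <- function(a, b, scope, paired) {
        # event-time shifts
        fb <- if (paired) {
            ok <- !is.na(a$firstBreakpoint) & !is.na(b$firstBreakpoint)
            list(a = a$firstBreakpoint[ok], b = b$firstBreakpoint[ok])
        } else list(a = a$firstBreakpoint[!is.na(a$firstBreakpoint)],
                    b = b$firstBreakpoint[!is.na(b$firstBreakpoint)])
        if (length(fb$a) >= 3L && length(fb$b) >= 3L) {
            dm <- deltaM(fb$a, fb$b, paired = paired, conf = conf)
            addRow("deltaM_firstBreakpoint", scope, dm$estimate, dm$ciLow,
                   dm$ciHigh, dm$nA, dm$nB)
        }
        pk <- if (paired) {
            ok <- !is.na(a$peakTime) & !is.na(b$peakTime)
            list(a = a$peakTime[ok], b = b$peakTime[ok],
                 upA = a$peakUpSlope[ok], upB = b$peakUpSlope[ok],
                 dnA = a$peakDownSlope[ok], dnB = b$peakDownSlope[ok])
        } else list(a = a$peakTime[!is.na(a$peakTime)],
                    b = b$peakTime[!is.na(b$peakTime)],
                    upA = a$peakUpSlope[!is.na(a$peakUpSlope)],
                    upB = b$peakUpSlope[!is.na(b$peakUpSlope)],
                    dnA = a$peakDownSlope[!is.na(a$peakDownSlope)],
                    dnB = b$peakDownSlope[!is.na(b$peakDownSlope)])
        if (length(pk$a) >= 3L && length(pk$b) >= 3L) {
            dm <- deltaM(pk$a, pk$b, paired = paired, conf = conf)
            addRow("deltaM_peakTime", scope, dm$estimate, dm$ciLow,
                   dm$ciHigh, dm$nA, dm$nB)
            ds <- deltaS(pk$upA, pk$upB, conf = conf, B = B,
                         seed = .deriveSeed(seed, 11L))
            addRow("deltaS_peakUp", scope, ds$estimate, ds$ciLow,
                   ds$ciHigh, ds$nA, ds$nB)
            ds <- deltaS(pk$dnA, pk$dnB, conf = conf, B = B,
                         seed = .deriveSeed(seed, 12L))
            addRow("deltaS_peakDown", scope, ds$estimate, ds$ciLow,
                   ds$ciHigh, ds$nA, ds$nB)
        }
        # onset and monotonicity proportions
        respA <- a$onset %in% c("immediate", "delayed")
        respB <- b$onset %in% c("immediate", "delayed")
        if (any(respA) && any(respB)) {
            dp <- deltaP(sum(a$onset == "immediate"), sum(respA),
                         sum(b$onset == "immediate"), sum(respB), conf)
            addRow("deltaP_immediate", scope, dp$estimate, dp$ciLow,
                   dp$ciHigh, dp$nA, dp$nB)
        }
        dp <- deltaP(sum(isMono(a)), nrow(a), sum(isMono(b)), nrow(b), conf)
        addRow("deltaP_monotonic", scope, dp$estimate, dp$ciLow, dp$ciHigh,
               dp$nA, dp$nB)
        # immediate first-segment slopes
        for (dir in c("up", "down")) {
            sa <- a$firstSlope[a$firstDirection == dir]
            sb <- b$firstSlope[b$firstDirection == dir]
            if (length(sa) >= 3L && length(sb) >= 3L &&
                stats::median(abs(sb)) > 0) {
                ds <- deltaS(sa, sb, conf = conf, B = B,
                             seed = .deriveSeed(seed,
                                 if (dir == "up") 13L else 14L))
                addRow(paste0("deltaS_immediate",
                              if (dir == "up") "Up" else "Down"),
                       scope, ds$estimate, ds$ciLow, ds$ciHigh, ds$nA, ds$nB)
            }
        }
    }
    dynA <- patternsA[patternsA$dynamic, , drop = FALSE]
    dynB <- patternsB[patternsB$dynamic, , drop = FALSE]
    if (!is.null(orthologs)) {
        om <- orthologMap(orthologs)
        a <- dynA[match(om$geneA, dynA$gene), , drop = FALSE]
        b <- dynB[match(om$geneB, dynB$gene), , drop = FALSE]
        both <- !is.na(a$gene) & !is.na(b$gene)
        statBlock(a[both, , drop = FALSE], b[both, , drop = FALSE],
                  "ortholog", paired = TRUE)
    }
    statBlock(dynA, dynB, "all", paired = FALSE)
    do.call(rbind, rows)
}

.fillDefaults <- function(x, defaults) {
    for (nm in names(defaults))
        if (is.null(x[[nm]])) x[[nm]] <- defaults[[nm]]
    x
}

.fitOptsFromList <- function(lst) {
    lst <- .fillDefaults(lst, list(maxBreakpoints = 5L, minSegPoints = 5L,
                                   directionAlpha = 0.2, r2Threshold = 0.2))
    fitOptions(lst$maxBreakpoints, lst$minSegPoints, lst$directionAlpha,
               lst$r2Threshold)
}

# Preprocess and fit one dataset; returns all per-dataset artifacts.
.processDataset <- function(tce, opts, exclude = NULL, cutpoints,
                            verbose = FALSE, log = function(...) invisible()) {
    nIn <- nrow(tce)
    if (!is.null(exclude) && length(exclude)) tce <- removeGenes(tce, exclude)
    tce <- medianRatioNormalize(tce)
    tce <- filterLowExpression(tce)
    tce <- scaleUnitInterval(tce)
    log(sprintf("retained %d / %d genes after preprocessing", nrow(tce), nIn))
    fits <- fitSegmentedModels(tce, opts, verbose = verbose)
    pat <- patternTable(fits)
    list(tce = tce, fits = fits, patterns = pat,
         fitTable = fitTable(fits),
         census = breakpointCensus(fits, cutpoints))
}

#' Run the full kinetics pipeline
#'
#' Executes, for two datasets (named A for the fast-sampled species and B for
#' the slow one), the complete chain: load or simulate counts, remove
#' excluded genes, median-ratio normalize, filter low expression, scale to
#' the unit interval, fit segmented models, classify patterns, census
#' breakpoints, and compute the cross-group comparison report. Deterministic
#' given the configuration and its seed; when \code{outDir} is given every
#' artifact is written as TSV together with a log and the configuration used.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{seed}{top-level integer seed; all stage seeds derive from it.}
#'     \item{simulate}{optional list (\code{nGenes}, \code{speedup},
#'       \code{dispersion}, \code{meanCountScale}, \code{sizeFactorSigma},
#'       \code{profileSeed}) requesting a paired-species simulation.}
#'     \item{datasets}{when not simulating: named list \code{A}/\code{B},
#'       each with \code{counts} (TSV path) and optional \code{exclude}
#'       (gene-list path).}
#'     \item{fitA, fitB}{fit-option lists (\code{maxBreakpoints},
#'       \code{minSegPoints}, \code{directionAlpha}, \code{r2Threshold});
#'       defaults use 5 minimum segment points for A and 3 for B.}
#'     \item{cutpoints}{census cutpoints in minutes (default 60, 100, 250).}
#'     \item{subsampleK}{optional k: additionally re-run dataset A on every
#'       k-th sample and recompute the comparison report.}
#'     \item{bootstrapB}{bootstrap resamples for slope-ratio CIs.}
#'   }
#' @param outDir optional output directory for the artifact bundle.
#' @param verbose print stage progress.
#' @return Invisible list with per-dataset results (\code{A}, \code{B}),
#'   \code{comparisons}, optional \code{subsampled} re-analysis, and the
#'   \code{orthologs} map.
#' @export
runPipeline <- function(config, outDir = NULL, verbose = FALSE) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    config <- .fillDefaults(config, list(
        seed = 1L, cutpoints = c(60, 100, 250), bootstrapB = 10000L,
        fitA = list(), fitB = list(minSegPoints = 3L)))
    logLines <- character(0)
    log <- function(...) {
        line <- sprintf(...)
        logLines <<- c(logLines, line)
        if (verbose) message(line)
    }
    optsA <- .fitOptsFromList(config$fitA)
    optsB <- .fitOptsFromList(.fillDefaults(config$fitB,
                                            list(minSegPoints = 3L)))
    orth <- NULL
    if (!is.null(config$simulate)) {
        sim <- .fillDefaults(config$simulate, list(
            nGenes = 300L, speedup = 2.5, dispersion = 0.05,
            meanCountScale = 500, sizeFactorSigma = 0.15,
            profileSeed = 101L))
        log("stage simulate: %d paired genes, speedup %.2f", sim$nGenes,
            sim$speedup)
        sc <- simConfig(nGenes = sim$nGenes, grid = mouseLikeGrid(),
                        dispersion = sim$dispersion,
                        meanCountScale = sim$meanCountScale,
                        sizeFactorSigma = sim$sizeFactorSigma,
                        kineticSpeedup = sim$speedup,
                        seed = .deriveSeed(config$seed, 1L),
                        profileSeed = sim$profileSeed)
        pair <- simulatePairedSpecies(sc)
        tceA <- pair$A
        tceB <- pair$B
        orth <- pair$orthologs
    } else {
        if (is.null(config$datasets) || is.null(config$datasets$A) ||
            is.null(config$datasets$B))
            .stageError("load", "config needs datasets$A and datasets$B (or simulate)")
        log("stage load: reading count matrices")
        tceA <- readCountMatrix(config$datasets$A$counts)
        tceB <- readCountMatrix(config$datasets$B$counts)
        if (!is.null(config$orthologs))
            orth <- loadOrthologMap(config$orthologs)
    }
    exA <- if (!is.null(config$datasets$A$exclude))
        readGeneList(config$datasets$A$exclude) else NULL
    exB <- if (!is.null(config$datasets$B$exclude))
        readGeneList(config$datasets$B$exclude) else NULL
    log("stage A: preprocess + fit (%d genes, %d samples)", nrow(tceA),
        ncol(tceA))
    resA <- .processDataset(tceA, optsA, exA, config$cutpoints, verbose, log)
    log("stage B: preprocess + fit (%d genes, %d samples)", nrow(tceB),
        ncol(tceB))
    resB <- .processDataset(tceB, optsB, exB, config$cutpoints, verbose, log)
    log("stage compare: %s", if (is.null(orth)) "all genes" else
        sprintf("%d ortholog pairs + all genes", nrow(orth)))
    cmp <- compareKinetics(resA$patterns, resB$patterns, orth,
                           B = config$bootstrapB,
                           seed = .deriveSeed(config$seed, 3L))
    out <- list(A = resA, B = resB, comparisons = cmp, orthologs = orth)
    if (!is.null(config$subsampleK)) {
        k <- config$subsampleK
        log("stage subsample: every %d-th sample of dataset A", k)
        subA <- subsampleEveryK(tceA, k = k)
        # the reduced-rate series keeps dataset A's fit parameters
        resSub <- .processDataset(subA, optsA, exA, config$cutpoints,
                                  verbose, log)
        out$subsampled <- list(
            A = resSub,
            comparisons = compareKinetics(resSub$patterns, resB$patterns,
                orth, B = config$bootstrapB,
                seed = .deriveSeed(config$seed, 4L)))
    }
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        wt <- function(df, name) utils::write.table(
            df, file.path(outDir, name), sep = "\t", quote = FALSE,
            row.names = FALSE)
        for (nm in c("A", "B")) {
            r <- out[[nm]]
            wt(r$fitTable, sprintf("%s_fit_table.tsv", nm))
            wt(r$patterns, sprintf("%s_pattern_table.tsv", nm))
            wt(r$census, sprintf("%s_breakpoint_census.tsv", nm))
            writeSizeFactors(r$tce, file.path(outDir,
                sprintf("%s_size_factors.tsv", nm)))
            if (!is.null(groundTruth(r$tce)))
                writeGroundTruth(r$tce, file.path(outDir,
                    sprintf("%s_ground_truth.tsv", nm)))
        }
        wt(cmp, "comparisons.tsv")
        if (!is.null(out$subsampled))
            wt(out$subsampled$comparisons, "comparisons_subsampled.tsv")
        yaml::write_yaml(config, file.path(outDir, "config_used.yaml"))
        writeLines(logLines, file.path(outDir, "pipeline_log.txt"))
    }
    out$log <- logLines
    invisible(out)
}
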