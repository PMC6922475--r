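#' Build a sampling-time grid
#'
#' Constructs the nominal grid \code{0, interval, 2*interval, ..., end} and
#' removes any \code{dropped} nominal times (samples lost to quality control).
#'
#' @param interval nominal sampling interval in minutes (must divide
#'   \code{end}).
#' @param end last nominal sampling time in minutes.
#' @param dropped numeric vector of nominal times to remove; every entry must
#'   lie on the nominal grid.
#'
#' @return A \linkS4class{TimeGrid}.
#'
#' @examples
#' length(gridTimes(makeTimeGrid(4, 600)))   # 151 samples
#' length(gridTimes(makeTimeGrid(10, 600)))  # 61 samples
#' @export
makeTimeGrid <- function(interval, end, dropped = numeric(0)) {
    if (length(interval) != 1L || !is.finite(interval) || interval <= 0)
        stop("interval must be a single positive number of minutes")
    if (abs(end %% interval) > 1e-8)
        stop("interval must divide the final time 'end'")
    nominal <- seq(0, end, by = interval)
    dropped <- as.numeric(dropped)
    if (length(dropped) && !all(dropped %in% nominal))
        stop("dropped times must lie on the nominal grid")
    times <- setdiff(nominal, dropped)
    new("TimeGrid", times = times, interval = as.numeric(interval),
        dropped = sort(dropped))
}

# Recover a TimeGrid from an arbitrary increasing set of times, inferring the
# nominal interval as the GCD of spacings when not supplied.
.timeGridFromTimes <- function(times, interval = NULL) {
    times <- as.numeric(times)
    if (is.null(interval)) interval <- .gcdAll(diff(times))
    nominal <- seq(min(times), max(times), by = interval)
    dropped <- nominal[!vapply(nominal,
        function(v) any(abs(times - v) < 1e-8), logical(1))]
    new("TimeGrid", times = times, interval = interval, dropped = dropped)
}

#' Study-like sampling grids
#'
#' Convenience grids matching the two dense minute-scale designs the package
#' is built around: a 4-minute mouse-like grid over 0--600 minutes with six
#' quality-control dropouts (145 samples) and a 10-minute human-like grid
#' (61 samples).
#'
#' @return A \linkS4class{TimeGrid}.
#' @examples
#' length(gridTimes(mouseLikeGrid()))  # 145
#' length(gridTimes(humanLikeGrid()))  # 61
#' @export
mouseLikeGrid <- function() {
    makeTimeGrid(4, 600, dropped = c(60, 132, 452, 464, 492, 512))
}

#' @rdname mouseLikeGrid
#' @export
humanLikeGrid <- function() makeTimeGrid(10, 600)

#' Time-grid accessors
#'
#' \code{gridTimes} returns the sampling times (minutes), \code{gridInterval}
#' the nominal spacing, \code{gridDropped} the removed nominal times, and
#' \code{timeGrid} the grid attached to a \linkS4class{TimeCourseExperiment}.
#'
#' @param x a \linkS4class{TimeGrid} or \linkS4class{TimeCourseExperiment}.
#' @return \code{timeGrid}: a \linkS4class{TimeGrid}; the others: numerics.
#' @name timeGrid
NULL

#' @rdname timeGrid
#' @export
setMethod("gridTimes", "TimeGrid", function(x) x@times)

#' @rdname timeGrid
#' @export
setMethod("gridInterval", "TimeGrid", function(x) x@interval)

#' @rdname timeGrid
#' @export
setMethod("gridDropped", "TimeGrid", function(x) x@dropped)

#' @rdname timeGrid
#' @export
setMethod("timeGrid", "TimeCourseExperiment", function(x) x@timeGrid)

#' @rdname timeGrid
#' @export
setMethod("gridTimes", "TimeCourseExperiment",
    function(x) x@timeGrid@times)

setMethod("show", "TimeGrid", function(object) {
    t <- object@times
    cat(sprintf(
        "TimeGrid: %d times, %g..%g min, nominal interval %g min, %d dropped\n",
        length(t), min(t), max(t), object@interval, length(object@dropped)))
})

setMethod("length", "TimeGrid", function(x) length(x@times))

#' Construct a timed count container
#'
#' Wraps a gene-by-sample matrix of nonnegative expected counts and its
#' \linkS4class{TimeGrid} into a \linkS4class{TimeCourseExperiment}. Column
#' names are set to \code{t<time>} (zero padded) and \code{colData$time}
#' records the sampling time of each column.
#'
#' @param counts numeric matrix, genes in rows (rownames = gene ids) and
#'   timed samples in columns, ordered by time.
#' @param grid a \linkS4class{TimeGrid} with one time per column.
#' @param rowData optional \code{DataFrame} of per-gene annotation.
#' @param metadata optional list stored in the experiment metadata.
#'
#' @return A \linkS4class{TimeCourseExperiment}.
#' @examples
#' g <- makeTimeGrid(10, 40)
#' m <- matrix(rpois(10, 50), 2, 5, dimnames = list(c("g1", "g2"), NULL))
#' tce <- TimeCourseExperiment(m, g)
#' gridTimes(tce)
#' @export
TimeCourseExperiment <- function(counts, grid, rowData = NULL,
                                 metadata = list()) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        stop("counts must have gene identifiers as rownames")
    colnames(counts) <- sampleIdsForTimes(grid@times)
    cd <- DataFrame(time = grid@times, row.names = colnames(counts))
    se <- SummarizedExperiment(assays = SimpleList(counts = counts),
                               colData = cd, metadata = metadata)
    if (!is.null(rowData)) rowData(se) <- rowData
    new("TimeCourseExperiment", se, timeGrid = grid)
}

#' Sample identifiers encoding time
#'
#' @param times numeric sampling times in minutes.
#' @return Character ids of the form \code{t0004}.
#' @export
sampleIdsForTimes <- function(times) sprintf("t%04d", round(times))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "TimeCourseExperiment", function(x) {
    metadata(x)$groundTruth
})

#' Simulation ground truth attached to an experiment
#'
#' For simulated data, returns the per-gene record of the true pattern class,
#' onset, breakpoints, slopes and peak time used by the generator
#' (\code{NULL} for real data).
#'
#' @param x a \linkS4class{TimeCourseExperiment}.
#' @return A \code{data.frame} or \code{NULL}.
#' @name groundTruth
NULL

setMethod("show", "TimeCourseExperiment", function(object) {
    callNextMethod()
    show(object@timeGrid)
})

#' @export
setMethod("[", c("TimeCourseExperiment", "ANY", "ANY"),
    function(x, i, j, ..., drop = FALSE) {
        out <- callNextMethod()
        if (!missing(j)) {
            jj <- seq_len(ncol(x))[j]
            times <- x@timeGrid@times[jj]
            if (length(times) < 2L)
                stop("subsetting must retain at least 2 samples")
            if (any(diff(times) <= 0))
                stop("column subsets must preserve time order")
            out@timeGrid <- .timeGridFromTimes(times,
                interval = x@timeGrid@interval)
        }
        out
    })
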