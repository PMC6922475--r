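#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData rowData<- colData<- assay<-
NULL

#' Sampling-time grid for a dense time course
#'
#' A \code{TimeGrid} records the sampling times (in minutes) of a time-course
#' experiment together with the nominal sampling interval and any nominal
#' times that were removed (e.g. samples failing quality control).
#'
#' @slot times numeric, strictly increasing nonnegative sampling times
#'   (minutes).
#' @slot interval numeric(1), nominal spacing between consecutive samples
#'   (minutes); every retained time is a multiple of it.
#' @slot dropped numeric, nominal times removed from the grid (minutes).
#'
#' @seealso [makeTimeGrid()], [mouseLikeGrid()], [humanLikeGrid()]
#' @export
setClass("TimeGrid",
    slots = c(times = "numeric", interval = "numeric", dropped = "numeric"))

setValidity("TimeGrid", function(object) {
    t <- object@times
    iv <- object@interval
    if (length(iv) != 1L || !is.finite(iv) || iv <= 0)
        return("interval must be a single positive number")
    if (length(t) < 2L)
        return("a time grid needs at least 2 sampling times")
    if (any(!is.finite(t)) || any(t < 0))
        return("times must be finite and nonnegative")
    if (any(diff(t) <= 0))
        return("times must be strictly increasing")
    if (any(abs(t %% iv) > 1e-8 & abs(t %% iv - iv) > 1e-8))
        return("every time must be a multiple of the nominal interval")
    if (length(object@dropped) && any(object@dropped %in% t))
        return("dropped times must not also appear in times")
    TRUE
})

#' Options controlling the segmented fit
#'
#' @slot maxBreakpoints integer(1), largest number of breakpoints considered
#'   (models with 0..maxBreakpoints breakpoints compete by BIC).
#' @slot minSegPoints integer(1), minimum number of observed time points each
#'   segment must contain for a model to be valid (5 for 4-minute grids,
#'   3 for 10-minute and week-long grids).
#' @slot directionAlpha numeric(1), per-segment slope p-value threshold above
#'   which a segment is labelled "same".
#' @slot r2Threshold numeric(1), adjusted R-squared gate above which a gene is
#'   called dynamic (0.2 for minute-scale series, 0.5 for week-long series).
#'
#' @seealso [fitOptions()]
#' @export
setClass("FitOptions",
    slots = c(maxBreakpoints = "integer", minSegPoints = "integer",
              directionAlpha = "numeric", r2Threshold = "numeric"))

setValidity("FitOptions", function(object) {
    if (object@maxBreakpoints < 0L) return("maxBreakpoints must be >= 0")
    if (object@minSegPoints < 2L) return("minSegPoints must be >= 2")
    a <- object@directionAlpha
    if (a <= 0 || a >= 1) return("directionAlpha must be in (0, 1)")
    TRUE
})

#' Gene-by-timed-sample count container
#'
#' A \code{TimeCourseExperiment} is a \linkS4class{SummarizedExperiment}
#' whose columns are timed samples described by a \linkS4class{TimeGrid}.
#' The primary assay \code{"counts"} holds nonnegative expected counts;
#' preprocessing adds \code{"normalized"} and \code{"scaled"} assays.
#'
#' @slot timeGrid the \linkS4class{TimeGrid} describing the columns.
#'
#' @seealso [TimeCourseExperiment()], [timeGrid()], [simulateTimeCourse()]
#' @export
setClass("TimeCourseExperiment",
    contains = "SummarizedExperiment",
    slots = c(timeGrid = "TimeGrid"))

setValidity("TimeCourseExperiment", function(object) {
    if (length(object@timeGrid@times) != ncol(object))
        return("timeGrid length must equal the number of samples")
    if (!"counts" %in% assayNames(object))
        return("a 'counts' assay is required")
    cts <- assay(object, "counts")
    if (any(cts < 0, na.rm = TRUE))
        return("counts must be nonnegative")
    rn <- rownames(object)
    if (is.null(rn) || anyDuplicated(rn))
        return("gene identifiers (rownames) must be present and unique")
    TRUE
})

#' Best segmented (breakpoint) fit for one gene
#'
#' Continuous piecewise-linear least-squares fit of a scaled expression
#' profile against time, with the number of breakpoints selected by BIC.
#' Segment \code{k} covers times \code{t <= b[k]} not covered by an earlier
#' segment (a point exactly at a breakpoint belongs to the left segment).
#'
#' @slot gene gene identifier.
#' @slot K integer(1), number of breakpoints.
#' @slot breakpoints numeric, strictly increasing breakpoint times (minutes).
#' @slot intercept numeric(1), fitted value extrapolated to t = 0.
#' @slot segmentSlopes numeric(K+1), slope of each segment in scaled
#'   expression units per minute.
#' @slot fitted numeric, fitted values at the observed times.
#' @slot rss residual sum of squares.
#' @slot bic Bayesian information criterion with p = 2 + 2K parameters.
#' @slot adjR2 adjusted R-squared with the same parameter count.
#' @slot segmentP two-sided t-test p-value per segment slope.
#' @slot directions per-segment label "up", "down" or "same".
#' @slot pointDirections the direction of the segment containing each sample.
#' @slot times observed times the fit was computed on.
#'
#' @seealso [fitSegmented()], [fitFixedBreakpoints()]
#' @export
setClass("SegmentedFit",
    slots = c(gene = "character", K = "integer", breakpoints = "numeric",
              intercept = "numeric", segmentSlopes = "numeric",
              fitted = "numeric", rss = "numeric", bic = "numeric",
              adjR2 = "numeric", segmentP = "numeric",
              directions = "character", pointDirections = "character",
              times = "numeric"))

setValidity("SegmentedFit", function(object) {
    K <- object@K
    if (length(object@breakpoints) != K)
        return("breakpoints length must equal K")
    if (K > 0L && any(diff(object@breakpoints) <= 0))
        return("breakpoints must be strictly increasing")
    if (length(object@segmentSlopes) != K + 1L)
        return("segmentSlopes length must equal K + 1")
    if (length(object@directions) != K + 1L)
        return("directions length must equal K + 1")
    TRUE
})

#' Collection of per-gene segmented fits
#'
#' @slot fits list of \linkS4class{SegmentedFit}, one per gene.
#' @slot options the \linkS4class{FitOptions} used.
#' @slot grid the \linkS4class{TimeGrid} the fits were computed on.
#' @slot geneIds gene identifiers, parallel to \code{fits}.
#'
#' @seealso [fitSegmentedModels()], [fitTable()], [dynamicGenes()]
#' @export
setClass("TrendFitSet",
    slots = c(fits = "list", options = "FitOptions", grid = "TimeGrid",
              geneIds = "character"))

setValidity("TrendFitSet", function(object) {
    if (length(object@fits) != length(object@geneIds))
        return("fits and geneIds must have the same length")
    TRUE
})
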