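# Pattern taxonomy over segment-direction sequences.
#
# Exact rule table (direction strings -> label):
#   up -> monotonic_up                down -> monotonic_down
#   up-down, up-same-down -> peak     down-up, down-same-up -> dip
#   same-up-down, same-up-same-down -> delayed_peak
#   same-down-up, same-down-same-up -> delayed_dip
#   same-up -> delayed_up             same-down -> delayed_down
#   up-same -> immediate_on           down-same -> immediate_off
#   anything else with at least two disconnected up or down segments
#   (e.g. up-down-up, up-down-down-up, up-same-down-up) -> cyclic
#
# Two conventions extend the table to sequences it leaves undefined:
# adjacent segments sharing a direction are collapsed first (up-up-down is
# treated as up-down), and when an otherwise-unmatched, non-cyclic sequence
# ends in "same" that trailing plateau is stripped and the rule table
# reapplied (up-same-down-same -> peak). An all-"same" sequence gets the
# extra label "flat".

.patternRules <- c(
    "up" = "monotonic_up", "down" = "monotonic_down",
    "up-down" = "peak", "up-same-down" = "peak",
    "down-up" = "dip", "down-same-up" = "dip",
    "same-up-down" = "delayed_peak", "same-up-same-down" = "delayed_peak",
    "same-down-up" = "delayed_dip", "same-down-same-up" = "delayed_dip",
    "same-up" = "delayed_up", "same-down" = "delayed_down",
    "up-same" = "immediate_on", "down-same" = "immediate_off")

.collapseDirections <- function(d) rle(d)$values

.matchPattern <- function(collapsed) {
    key <- paste(collapsed, collapse = "-")
    if (key %in% names(.patternRules))
        return(unname(.patternRules[key]))
    moves <- collapsed[collapsed != "same"]
    if (sum(moves == "up") >= 2L || sum(moves == "down") >= 2L)
        return("cyclic")
    if (length(collapsed) > 1L && collapsed[length(collapsed)] == "same")
        return(.matchPattern(collapsed[-length(collapsed)]))
    "flat"
}

#' Classify a direction sequence into the pattern taxonomy
#'
#' Maps a gene's per-segment direction sequence to one of: monotonic up/down,
#' (delayed) peak, (delayed) dip, delayed up/down, immediate on/off, cyclic,
#' flat, or not_dynamic when the gene fails the adjusted R-squared gate.
#' The onset is \code{"immediate"} when the first segment is already up or
#' down, \code{"delayed"} when a flat segment precedes the first response,
#' and \code{"none"} for flat or non-dynamic genes.
#'
#' @param directions character vector of per-segment directions
#'   (\code{"up"}, \code{"down"}, \code{"same"}).
#' @param K number of breakpoints; must equal
#'   \code{length(directions) - 1}.
#' @param dynamic logical; did the gene pass the adjusted R-squared gate?
#' @return List with \code{label} and \code{onset}.
#' @examples
#' patternLabel(c("up", "down"), 1)           # peak, immediate
#' patternLabel(c("same", "up", "down"), 2)   # delayed_peak, delayed
#' patternLabel(c("up", "down", "up"), 2)     # cyclic
#' @export
patternLabel <- function(directions, K = length(directions) - 1L,
                         dynamic = TRUE) {
    if (!all(directions %in% c("up", "down", "same")))
        stop("unknown direction symbol: directions must be up/down/same")
    if (length(directions) != K + 1L)
        stop("directions must have length K + 1")
    if (!isTRUE(dynamic))
        return(list(label = "not_dynamic", onset = "none"))
    collapsed <- .collapseDirections(directions)
    label <- .matchPattern(collapsed)
    onset <- if (label == "flat") "none"
             else if (collapsed[1L] != "same") "immediate"
             else "delayed"
    list(label = label, onset = onset)
}

#' Extract peaks from a segmented fit
#'
#' A peak is an up segment followed -- optionally through a no-change
#' plateau -- by a down segment; its time is the breakpoint ending the up
#' segment, its up slope the slope of the segment before that breakpoint and
#' its down slope the slope of the first following down segment. Peaks are
#' returned in time order with \code{rank} 1 for the first.
#'
#' @param fit a \linkS4class{SegmentedFit}.
#' @return \code{data.frame} with columns \code{peakTime}, \code{upSlope},
#'   \code{downSlope}, \code{rank} (zero rows when the gene has no peak).
#' @export
detectPeaks <- function(fit) {
    .scanPeaks(fit@directions, fit@breakpoints, fit@segmentSlopes)
}

# Direction-sequence peak scan shared by detectPeaks and the synthetic
# ground-truth builder.
.scanPeaks <- function(directions, breakpoints, slopes) {
    runs <- rle(directions)
    ends <- cumsum(runs$lengths)        # last segment index of each run
    starts <- ends - runs$lengths + 1L
    out <- data.frame(peakTime = numeric(0), upSlope = numeric(0),
                      downSlope = numeric(0), rank = integer(0))
    for (j in seq_along(runs$values)) {
        if (runs$values[j] != "up") next
        nxt <- j + 1L
        downAt <- if (nxt <= length(runs$values) &&
                      runs$values[nxt] == "down") nxt
                  else if (nxt + 1L <= length(runs$values) &&
                           runs$values[nxt] == "same" &&
                           runs$values[nxt + 1L] == "down") nxt + 1L
                  else NA_integer_
        if (is.na(downAt)) next
        segUpEnd <- ends[j]
        out <- rbind(out, data.frame(
            peakTime = breakpoints[segUpEnd],
            upSlope = slopes[segUpEnd],
            downSlope = slopes[starts[downAt]],
            rank = 0L))
    }
    if (nrow(out)) {
        out <- out[order(out$peakTime), , drop = FALSE]
        out$rank <- seq_len(nrow(out))
        rownames(out) <- NULL
    }
    out
}

#' Onset class of a fitted trend
#'
#' \code{"immediate"} when the first segment is up or down (a response within
#' the minimum-segment window: 20 minutes on a 4-minute grid, 30 on a
#' 10-minute grid), \code{"delayed"} when a flat segment precedes a later
#' response, \code{"none"} when no segment moves.
#'
#' @param fit a \linkS4class{SegmentedFit}.
#' @return Character scalar.
#' @export
onsetClass <- function(fit) {
    d <- fit@directions
    if (d[1L] != "same") return("immediate")
    if (any(d != "same")) return("delayed")
    "none"
}

#' Time of the first breakpoint
#'
#' The first breakpoint marks the end of the initial response; genes without
#' breakpoints (monotonic trends) return \code{NA}.
#'
#' @param fit a \linkS4class{SegmentedFit}.
#' @return Numeric scalar (minutes) or \code{NA}.
#' @export
firstBreakpoint <- function(fit) {
    if (fit@K == 0L) NA_real_ else fit@breakpoints[1L]
}

#' Count breakpoints occurring before cutpoint times
#'
#' Tallies, across all dynamic genes, the breakpoints falling strictly before
#' each cutpoint and the number of distinct genes contributing at least one
#' (a gene with several early breakpoints contributes each of them to the
#' breakpoint count but only once to the gene count).
#'
#' @param fits a \linkS4class{TrendFitSet} or list of
#'   \linkS4class{SegmentedFit}.
#' @param cutpoints numeric cutpoint times in minutes
#'   (default \code{c(60, 100, 250)}).
#' @param gate adjusted R-squared gate for inclusion; \code{NULL} uses the
#'   fit set's option (list inputs default to 0.2).
#' @return \code{data.frame} with \code{cutpoint}, \code{nBreakpoints},
#'   \code{nGenes}.
#' @export
breakpointCensus <- function(fits, cutpoints = c(60, 100, 250), gate = NULL) {
    if (is(fits, "TrendFitSet")) {
        if (is.null(gate)) gate <- fits@options@r2Threshold
        fits <- fits@fits
    }
    if (is.null(gate)) gate <- 0.2
    fits <- Filter(function(f) !is.na(f@adjR2) && f@adjR2 > gate, fits)
    bps <- lapply(fits, function(f) f@breakpoints)
    data.frame(
        cutpoint = cutpoints,
        nBreakpoints = vapply(cutpoints,
            function(cp) sum(vapply(bps, function(b) sum(b < cp), 0L)),
            0L),
        nGenes = vapply(cutpoints,
            function(cp) sum(vapply(bps, function(b) any(b < cp), FALSE)),
            0L))
}

#' Pattern table for a fit set
#'
#' One row per gene: taxonomy label, onset, breakpoint count, first
#' breakpoint, and first-peak summaries (only the first peak feeds downstream
#' peak statistics).
#'
#' @param fits a \linkS4class{TrendFitSet}.
#' @param gate adjusted R-squared gate (defaults to the fit options').
#' @return A \code{data.frame}.
#' @export
patternTable <- function(fits, gate = NULL) {
    stopifnot(is(fits, "TrendFitSet"))
    if (is.null(gate)) gate <- fits@options@r2Threshold
    rows <- lapply(fits@fits, function(f) {
        dyn <- !is.na(f@adjR2) && f@adjR2 > gate
        pl <- patternLabel(f@directions, f@K, dynamic = dyn)
        pk <- if (dyn) detectPeaks(f) else
            data.frame(peakTime = numeric(0), upSlope = numeric(0),
                       downSlope = numeric(0), rank = integer(0))
        data.frame(
            gene = f@gene, label = pl$label, onset = pl$onset, K = f@K,
            adjR2 = f@adjR2, dynamic = dyn,
            firstDirection = f@directions[1L],
            firstSlope = f@segmentSlopes[1L],
            firstBreakpoint = firstBreakpoint(f),
            nPeaks = nrow(pk),
            peakTime = if (nrow(pk)) pk$peakTime[1L] else NA_real_,
            peakUpSlope = if (nrow(pk)) pk$upSlope[1L] else NA_real_,
            peakDownSlope = if (nrow(pk)) pk$downSlope[1L] else NA_real_,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
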