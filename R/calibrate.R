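#' Permutation calibration of the adjusted R-squared gate
#'
#' Estimates a null distribution for the adjusted R-squared of the best
#' segmented fit by repeatedly shuffling the sample order (one shared
#' permutation per round, destroying the time structure while preserving each
#' gene's marginal distribution), refitting every gene, and pooling the
#' resulting adjusted R-squared values. The recommended dynamic-gene cutoff
#' is the \code{1 - alpha} quantile of that null distribution.
#'
#' @param scaled numeric matrix of unit-interval-scaled profiles (genes x
#'   samples), or a \linkS4class{TimeCourseExperiment} with a \code{"scaled"}
#'   assay.
#' @param grid a \linkS4class{TimeGrid} or numeric time vector (taken from
#'   the experiment when omitted).
#' @param nPerm number of permutation rounds.
#' @param seed integer seed making the shuffles reproducible.
#' @param opts a \linkS4class{FitOptions} used for the null fits.
#' @param alpha tail probability of the null retained above the cutoff
#'   (default 0.05).
#' @return List with \code{threshold} (the \code{1 - alpha} null quantile)
#'   and \code{null} (all permuted adjusted R-squared values).
#' @export
permutationR2Threshold <- function(scaled, grid = NULL, nPerm = 20L,
                                   seed = 1L, opts = fitOptions(),
                                   alpha = 0.05) {
    if (is(scaled, "TimeCourseExperiment")) {
        if (is.null(grid)) grid <- timeGrid(scaled)
        scaled <- assay(scaled, "scaled")
    }
    if (is.null(grid)) stop("a time grid is required")
    t <- .gridTimesOf(grid)
    if (ncol(scaled) != length(t))
        stop("matrix columns must match the time grid")
    if (nPerm < 1L) stop("nPerm must be at least 1")
    if (nrow(scaled) == 0L) stop("matrix too small to fit")
    nullR2 <- .withSeed(seed, {
        vals <- numeric(0)
        for (r in seq_len(nPerm)) {
            perm <- sample.int(length(t))
            r2 <- apply(scaled[, perm, drop = FALSE], 1L, function(x) {
                fitSegmented(x, t, opts)@adjR2
            })
            vals <- c(vals, r2)
        }
        vals
    })
    nullR2 <- nullR2[!is.na(nullR2)]
    list(threshold = unname(stats::quantile(nullR2, 1 - alpha, type = 7)),
         null = nullR2)
}
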