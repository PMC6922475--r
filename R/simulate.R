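# Synthetic minute-scale time courses with known piecewise-linear kinetics
# and negative-binomial count noise, so every downstream stage can be
# validated against recorded ground truth.

.patternTemplates <- list(
    monotonic_up   = c("up"),
    monotonic_down = c("down"),
    peak           = c("up", "down"),
    delayed_peak   = c("same", "up", "down"),
    dip            = c("down", "up"),
    delayed_dip    = c("same", "down", "up"),
    delayed_up     = c("same", "up"),
    delayed_down   = c("same", "down"),
    immediate_on   = c("up", "same"),
    immediate_off  = c("down", "same"),
    cyclic         = c("up", "down", "up"))

.defaultPatternMix <- c(
    monotonic_up = 0.12, monotonic_down = 0.12, peak = 0.18,
    delayed_peak = 0.08, dip = 0.10, delayed_dip = 0.05,
    delayed_up = 0.06, delayed_down = 0.05, immediate_on = 0.08,
    immediate_off = 0.08, cyclic = 0.08)

#' Simulation configuration
#'
#' Bundles and validates the knobs of the synthetic time-course generator.
#' Two seeds are kept separate so that ground truth is a function of
#' \code{profileSeed} only: changing \code{seed} redraws the count noise but
#' leaves the true kinetics untouched.
#'
#' @param nGenes number of genes to simulate.
#' @param grid a \linkS4class{TimeGrid} (default [mouseLikeGrid()]).
#' @param dispersion negative-binomial dispersion \eqn{\phi \ge 0}
#'   (variance \eqn{\mu + \phi\mu^2}); 0 gives Poisson noise.
#' @param meanCountScale expected-count magnitude: a scaled expression x maps
#'   to mean count \code{meanCountScale * (0.1 + 0.9 x)}, keeping all means
#'   positive so geometric means exist.
#' @param sizeFactorSigma log-normal sd of per-sample library-size factors
#'   (median-centered to 1, so median-ratio normalization is their inverse).
#' @param patternMix named probabilities over the pattern classes (must sum
#'   to 1; names from \code{names(.patternTemplates)}).
#' @param kineticSpeedup factor by which a paired fast species' breakpoints
#'   are compressed (and slopes steepened) relative to the slow species.
#' @param segMinMinutes minimum duration (minutes) of every moving segment.
#' @param delayRange range (minutes) of the initial flat segment of delayed
#'   patterns.
#' @param excursion range of the total scaled-expression change per moving
#'   segment before unit rescaling.
#' @param nStableGenes number of additional non-responding background genes
#'   (constant mean, NB noise). Real transcriptomes are mostly stable; a
#'   stable majority is also what makes the median-ratio size-factor
#'   assumption (most genes unchanged) hold on synthetic data, and it gives
#'   the adjusted R-squared gate genes it must reject. Default 1.5x
#'   \code{nGenes}.
#' @param stableLevelRange range of constant expected counts for stable
#'   genes, drawn log-uniformly (levels below the mean filter exercise it).
#' @param seed integer seed for count noise.
#' @param profileSeed integer seed for the true kinetic parameters.
#' @param exact if \code{TRUE}, [simulateCounts()] returns the expected
#'   counts themselves (no sampling): a noiseless mode for exactness tests.
#' @return A validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nGenes = 500L, grid = mouseLikeGrid(),
                      dispersion = 0.05, meanCountScale = 500,
                      sizeFactorSigma = 0.15,
                      patternMix = .defaultPatternMix,
                      kineticSpeedup = 1, segMinMinutes = 60,
                      delayRange = c(40, 160), excursion = c(0.5, 1),
                      nStableGenes = round(1.5 * nGenes),
                      stableLevelRange = c(5, 2000),
                      seed = 1L, profileSeed = 101L, exact = FALSE) {
    if (abs(sum(patternMix) - 1) > 1e-8)
        stop("patternMix probabilities must sum to 1")
    if (!all(names(patternMix) %in% names(.patternTemplates)))
        stop("unknown pattern class in patternMix")
    if (dispersion < 0) stop("dispersion must be >= 0")
    if (kineticSpeedup <= 0) stop("kineticSpeedup must be positive")
    structure(list(nGenes = as.integer(nGenes), grid = grid,
                   dispersion = dispersion, meanCountScale = meanCountScale,
                   sizeFactorSigma = sizeFactorSigma, patternMix = patternMix,
                   kineticSpeedup = kineticSpeedup,
                   segMinMinutes = segMinMinutes, delayRange = delayRange,
                   excursion = excursion,
                   nStableGenes = as.integer(nStableGenes),
                   stableLevelRange = stableLevelRange,
                   seed = as.integer(seed),
                   profileSeed = as.integer(profileSeed), exact = exact),
              class = "SimConfig")
}

# Continuous piecewise-linear curve from baseline/breakpoints/slopes.
.piecewiseCurve <- function(times, baseline, breakpoints, slopes) {
    y <- baseline + slopes[1L] * times
    for (k in seq_along(breakpoints))
        y <- y + (slopes[k + 1L] - slopes[k]) * pmax(times - breakpoints[k], 0)
    y
}

# Draw one true pattern: breakpoints and slopes on the latent time span.
.randomSpec <- function(class, span, segMin, delayRange, excursion) {
    dirs <- .patternTemplates[[class]]
    if (class == "cyclic" && stats::runif(1) < 0.5)
        dirs <- c("down", "up", "down")
    K <- length(dirs) - 1L
    delayed <- dirs[1L] == "same"
    if (delayed) {
        delay <- stats::runif(1, delayRange[1L], delayRange[2L])
        rest <- span - delay - K * segMin
        u <- stats::runif(K)
        gaps <- c(delay, segMin + u / sum(u) * rest)
    } else {
        u <- stats::runif(K + 1L)
        gaps <- segMin + u / sum(u) * (span - (K + 1L) * segMin)
    }
    b <- cumsum(gaps)[seq_len(K)]
    mag <- stats::runif(K + 1L, excursion[1L], excursion[2L]) / gaps
    slopes <- ifelse(dirs == "up", mag, ifelse(dirs == "down", -mag, 0))
    firstMove <- dirs[dirs != "same"][1L]
    baseline <- if (identical(firstMove, "down"))
        stats::runif(1, 0.85, 1) else stats::runif(1, 0, 0.15)
    list(class = class, baseline = baseline, breakpoints = b,
         slopes = unname(slopes))
}

# Ground truth visible on a grid: rescales the curve to the unit interval,
# keeps breakpoints interior to the observation window, and derives labels
# with the same pattern rules the fitting side uses.
.truthFromSpec <- function(spec, times) {
    curve <- .piecewiseCurve(times, spec$baseline, spec$breakpoints,
                             spec$slopes)
    rng <- max(curve) - min(curve)
    t1 <- times[1L]
    tN <- times[length(times)]
    if (rng <= 1e-12) {
        return(list(curve = rep(0, length(times)),
                    truth = data.frame(class = spec$class, label = "flat",
                        onset = "none", nBreakpoints = 0L,
                        firstBreakpoint = NA_real_, peakTime = NA_real_,
                        breakpoints = "", slopes = "",
                        stringsAsFactors = FALSE)))
    }
    scaled <- (curve - min(curve)) / rng
    vis <- spec$breakpoints > t1 & spec$breakpoints < tN
    b <- spec$breakpoints[vis]
    firstSeg <- sum(spec$breakpoints <= t1) + 1L
    lastSeg <- sum(spec$breakpoints < tN) + 1L
    slopes <- spec$slopes[firstSeg:lastSeg] / rng
    dirs <- ifelse(slopes > 1e-12, "up",
                   ifelse(slopes < -1e-12, "down", "same"))
    pl <- patternLabel(dirs, length(b), dynamic = TRUE)
    pk <- .scanPeaks(dirs, b, slopes)
    list(curve = scaled,
         truth = data.frame(class = spec$class, label = pl$label,
             onset = pl$onset, nBreakpoints = length(b),
             firstBreakpoint = if (length(b)) b[1L] else NA_real_,
             peakTime = if (nrow(pk)) pk$peakTime[1L] else NA_real_,
             breakpoints = .commaJoin(b), slopes = .commaJoin(slopes),
             stringsAsFactors = FALSE))
}

#' Simulate true scaled mean curves
#'
#' Draws a pattern class per gene from \code{patternMix}, realizes random
#' breakpoints and slopes for it, evaluates the continuous piecewise-linear
#' mean curve on the grid, and rescales it to the unit interval. Ground
#' truth (class, visible breakpoints, scaled slopes, onset, first peak) is
#' recorded per gene. Deterministic given \code{profileSeed}.
#'
#' @param config a [simConfig()].
#' @param genePrefix prefix for generated gene identifiers.
#' @return List with \code{curves} (genes x times matrix in \[0,1\]; stable
#'   background genes are constant rows), \code{truth} (\code{data.frame},
#'   one row per gene), \code{specs} (the latent pattern parameters of the
#'   dynamic genes) and \code{countScale} (per-gene expected-count
#'   magnitude).
#' @export
simulateProfiles <- function(config, genePrefix = "gene") {
    stopifnot(inherits(config, "SimConfig"))
    times <- gridTimes(config$grid)
    span <- max(times) - min(times)
    .withSeed(config$profileSeed, {
        classes <- sample(names(config$patternMix), config$nGenes,
                          replace = TRUE, prob = config$patternMix)
        specs <- lapply(classes, .randomSpec, span = span,
                        segMin = config$segMinMinutes,
                        delayRange = config$delayRange,
                        excursion = config$excursion)
        out <- lapply(specs, .truthFromSpec, times = times)
        curves <- do.call(rbind, lapply(out, `[[`, "curve"))
        truth <- do.call(rbind, lapply(out, `[[`, "truth"))
        countScale <- rep(config$meanCountScale, config$nGenes)
        if (config$nStableGenes > 0L) {
            stable <- .stableBackground(config, length(times))
            curves <- rbind(curves, stable$curves)
            truth <- rbind(truth, stable$truth)
            countScale <- c(countScale, stable$countScale)
        }
        ids <- sprintf("%s%04d", genePrefix, seq_len(nrow(curves)))
        rownames(curves) <- ids
        truth <- cbind(data.frame(gene = ids, stringsAsFactors = FALSE),
                       truth)
        rownames(truth) <- NULL
        list(curves = curves, truth = truth, specs = specs,
             countScale = countScale)
    })
}

# Non-responding background genes: constant mean at a log-uniform level.
# The scaled curve is 0, so the count mean is 0.1 * countScale = level.
.stableBackground <- function(config, nTimes) {
    nS <- config$nStableGenes
    lvl <- exp(stats::runif(nS, log(config$stableLevelRange[1L]),
                            log(config$stableLevelRange[2L])))
    list(curves = matrix(0, nS, nTimes),
         truth = data.frame(class = rep("stable", nS),
             label = "not_dynamic", onset = "none", nBreakpoints = 0L,
             firstBreakpoint = NA_real_, peakTime = NA_real_,
             breakpoints = "", slopes = "", stringsAsFactors = FALSE),
         countScale = 10 * lvl)
}

#' Draw negative-binomial counts around mean curves
#'
#' Maps each scaled mean curve x to expected counts
#' \code{meanCountScale * (0.1 + 0.9 x)}, multiplies by log-normal per-sample
#' size factors (median-centered to 1), and draws counts with variance
#' \eqn{\mu + \phi \mu^2} (Poisson when \eqn{\phi = 0}; the expected counts
#' themselves when \code{config$exact}). Reproducible given
#' \code{config$seed}.
#'
#' @param curves genes x times matrix of scaled means in \[0,1\].
#' @param config a [simConfig()].
#' @param countScale optional per-gene expected-count magnitude (defaults to
#'   \code{meanCountScale} for every row).
#' @return List with \code{counts} (genes x samples) and
#'   \code{sizeFactors}.
#' @export
simulateCounts <- function(curves, config, countScale = NULL) {
    stopifnot(inherits(config, "SimConfig"))
    if (is.null(countScale))
        countScale <- rep(config$meanCountScale, nrow(curves))
    mu <- countScale * (0.1 + 0.9 * curves)
    if (any(mu < 0)) stop("negative expected counts")
    nS <- ncol(mu)
    .withSeed(config$seed, {
        sf <- exp(stats::rnorm(nS, 0, config$sizeFactorSigma))
        sf <- sf / stats::median(sf)
        muS <- sweep(mu, 2L, sf, "*")
        counts <- if (config$exact) {
            muS
        } else if (config$dispersion == 0) {
            matrix(stats::rpois(length(muS), muS), nrow(muS), ncol(muS))
        } else {
            matrix(stats::rnbinom(length(muS), mu = muS,
                                  size = 1 / config$dispersion),
                   nrow(muS), ncol(muS))
        }
        dimnames(counts) <- dimnames(mu)
        list(counts = counts, sizeFactors = sf)
    })
}

#' Simulate a complete timed count experiment
#'
#' Composes [simulateProfiles()] and [simulateCounts()] into a
#' \linkS4class{TimeCourseExperiment} whose metadata carries the ground
#' truth (retrievable with [groundTruth()]).
#'
#' @inheritParams simulateProfiles
#' @return A \linkS4class{TimeCourseExperiment}.
#' @examples
#' tce <- simulateTimeCourse(simConfig(nGenes = 5, grid = humanLikeGrid()))
#' head(groundTruth(tce))
#' @export
simulateTimeCourse <- function(config, genePrefix = "gene") {
    prof <- simulateProfiles(config, genePrefix)
    cts <- simulateCounts(prof$curves, config, prof$countScale)
    TimeCourseExperiment(cts$counts, config$grid,
        metadata = list(groundTruth = prof$truth,
                        trueSizeFactors = cts$sizeFactors,
                        simConfig = config))
}

#' Simulate an ortholog-paired fast/slow species contrast
#'
#' Generates latent kinetics for a fast species A on its grid, then derives
#' each ortholog's slow-species profile by stretching time by
#' \code{kineticSpeedup} (breakpoints multiplied, slopes divided). Slow
#' breakpoints pushed beyond the observation window become invisible, so the
#' slow species shows later first breakpoints and more monotonic genes --
#' the kinetic signature the comparison statistics are built to measure.
#'
#' @param config a [simConfig()] describing species A (its \code{grid} and
#'   \code{kineticSpeedup} > 1).
#' @param gridB the slow species' \linkS4class{TimeGrid}
#'   (default [humanLikeGrid()]).
#' @return List with \code{A} and \code{B}
#'   (\linkS4class{TimeCourseExperiment}s) and \code{orthologs}
#'   (two-column 1:1 map).
#' @export
simulatePairedSpecies <- function(config, gridB = humanLikeGrid()) {
    stopifnot(inherits(config, "SimConfig"))
    profA <- simulateProfiles(config, genePrefix = "gA_")
    timesB <- gridTimes(gridB)
    sp <- config$kineticSpeedup
    outB <- lapply(profA$specs, function(s) {
        sB <- list(class = s$class, baseline = s$baseline,
                   breakpoints = s$breakpoints * sp,
                   slopes = s$slopes / sp)
        .truthFromSpec(sB, timesB)
    })
    curvesB <- do.call(rbind, lapply(outB, `[[`, "curve"))
    truthB <- do.call(rbind, lapply(outB, `[[`, "truth"))
    if (config$nStableGenes > 0L) {
        # orthologous background genes: same constant levels in both species
        nS <- config$nStableGenes
        idxS <- config$nGenes + seq_len(nS)
        stableTruth <- profA$truth[idxS, setdiff(colnames(profA$truth),
                                                 "gene"), drop = FALSE]
        curvesB <- rbind(curvesB, matrix(0, nS, length(timesB)))
        truthB <- rbind(truthB, stableTruth)
    }
    idsB <- sprintf("gB_%04d", seq_len(nrow(curvesB)))
    rownames(curvesB) <- idsB
    truthB <- cbind(data.frame(gene = idsB, stringsAsFactors = FALSE),
                    truthB)
    rownames(truthB) <- NULL
    ctsA <- simulateCounts(profA$curves, config, profA$countScale)
    cfgB <- config
    cfgB$grid <- gridB
    cfgB$seed <- .deriveSeed(config$seed, 2L)
    ctsB <- simulateCounts(curvesB, cfgB, profA$countScale)
    A <- TimeCourseExperiment(ctsA$counts, config$grid,
        metadata = list(groundTruth = profA$truth,
                        trueSizeFactors = ctsA$sizeFactors))
    B <- TimeCourseExperiment(ctsB$counts, gridB,
        metadata = list(groundTruth = truthB,
                        trueSizeFactors = ctsB$sizeFactors))
    list(A = A, B = B,
         orthologs = data.frame(geneA = rownames(A), geneB = idsB,
                                stringsAsFactors = FALSE))
}
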