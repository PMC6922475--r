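test_that("pattern labels handle onset, gating and degenerate sequences", {
    expect_identical(patternLabel(c("up", "down"), 1),
                     list(label = "peak", onset = "immediate"))
    expect_identical(patternLabel(c("same", "up", "down"), 2)$onset,
                     "delayed")
    expect_identical(patternLabel(c("up"), 0, dynamic = FALSE),
                     list(label = "not_dynamic", onset = "none"))
    expect_identical(patternLabel(c("same", "same"), 1),
                     list(label = "flat", onset = "none"))
    expect_error(patternLabel(c("up", "sideways"), 1), "unknown direction")
    expect_error(patternLabel(c("up", "down"), 2), "length")
    # adjacent same-direction segments collapse before matching
    expect_identical(patternLabel(c("up", "up", "down"), 2)$label, "peak")
    expect_identical(patternLabel(c("same", "same", "up"), 2)$label,
                     "delayed_up")
    # a trailing plateau on an otherwise-matched shape keeps its label
    expect_identical(patternLabel(c("up", "same", "down", "same"), 3)$label,
                     "peak")
    expect_identical(patternLabel(c("same", "up", "same"), 2)$label,
                     "delayed_up")
    # two disconnected moves in one direction are cyclic
    expect_identical(patternLabel(c("up", "same", "up"), 2)$label, "cyclic")
})

test_that("labelling is total and deterministic on the direction alphabet", {
    set.seed(4)
    allowed <- c("not_dynamic", "monotonic_up", "monotonic_down", "peak",
                 "delayed_peak", "dip", "delayed_dip", "delayed_up",
                 "delayed_down", "immediate_on", "immediate_off", "cyclic",
                 "flat")
    for (i in 1:200) {
        d <- sample(c("up", "down", "same"), sample(1:6, 1), replace = TRUE)
        lab <- patternLabel(d)
        expect_true(lab$label %in% allowed)
        expect_identical(lab, patternLabel(d))
        expect_identical(
            lab$onset,
            if (lab$label == "flat") "none"
            else if (d[d != "same"][1] == d[1]) "immediate" else "delayed")
    }
})

mkFit <- function(directions, b, slopes = NULL) {
    if (is.null(slopes))
        slopes <- ifelse(directions == "up", 0.01,
                         ifelse(directions == "down", -0.01, 0))
    K <- length(b)
    new("SegmentedFit", gene = "g", K = as.integer(K), breakpoints = b,
        intercept = 0, segmentSlopes = slopes, fitted = numeric(0),
        rss = 0, bic = 0, adjR2 = 0.9, segmentP = rep(0, K + 1L),
        directions = directions, pointDirections = character(0),
        times = numeric(0))
}

test_that("peaks are scanned through optional plateaus, in time order", {
    one <- detectPeaks(mkFit(c("up", "down"), 240))
    expect_equal(one$peakTime, 240)
    expect_equal(one$rank, 1L)
    expect_gt(one$upSlope, 0)
    expect_lt(one$downSlope, 0)
    plateau <- detectPeaks(mkFit(c("up", "same", "down"), c(200, 280)))
    expect_equal(plateau$peakTime, 200)  # breakpoint ending the up segment
    expect_equal(nrow(detectPeaks(mkFit(c("down", "up"), 300))), 0L)
    cyc <- detectPeaks(mkFit(c("up", "down", "up", "down"),
                             c(100, 200, 300)))
    expect_equal(cyc$peakTime, c(100, 300))
    expect_equal(cyc$rank, c(1L, 2L))
})

test_that("onset and first breakpoint follow the direction sequence", {
    expect_identical(onsetClass(mkFit(c("up", "down"), 100)), "immediate")
    expect_identical(onsetClass(mkFit(c("same", "up"), 100)), "delayed")
    expect_identical(onsetClass(mkFit(c("same", "same"), 100)), "none")
    expect_equal(firstBreakpoint(mkFit(c("up"), numeric(0))), NA_real_)
    expect_equal(firstBreakpoint(mkFit(c("up", "down", "up"), c(88, 300))),
                 88)
})

test_that("breakpoint census counts breakpoints and genes separately", {
    fits <- list(mkFit(c("up", "down"), 10),
                 mkFit(c("up", "down", "up"), c(70, 300)))
    cen <- breakpointCensus(fits, cutpoints = 60)
    expect_equal(cen$nBreakpoints, 1L)
    expect_equal(cen$nGenes, 1L)
    multi <- breakpointCensus(list(mkFit(c("up", "down", "up"), c(20, 40))),
                              cutpoints = 60)
    expect_equal(multi$nBreakpoints, 2L)
    expect_equal(multi$nGenes, 1L)
    none <- breakpointCensus(list(), cutpoints = c(60, 100, 250))
    expect_equal(none$nBreakpoints, c(0L, 0L, 0L))
    # non-dynamic fits are excluded from every census
    weak <- mkFit(c("up", "down"), 10)
    weak@adjR2 <- 0.1
    expect_equal(breakpointCensus(list(weak), cutpoints = 60)$nBreakpoints,
                 0L)
})

test_that("noiseless synthetic peaks are re-detected at the true time", {
    cfg <- simConfig(nGenes = 12, nStableGenes = 30, grid = mouseLikeGrid(),
                     patternMix = c(peak = 1), exact = TRUE,
                     sizeFactorSigma = 0, profileSeed = 31)
    tce <- quietly(scaleUnitInterval(filterLowExpression(
        medianRatioNormalize(simulateTimeCourse(cfg)))))
    fits <- fitSegmentedModels(tce, fitOptions(minSegPoints = 5))
    gt <- groundTruth(simulateTimeCourse(cfg))
    for (g in rownames(tce)) {
        pk <- detectPeaks(fits[[g]])
        expect_gt(nrow(pk), 0)
        expect_lt(abs(pk$peakTime[1] - gt$peakTime[gt$gene == g]),
                  gridInterval(mouseLikeGrid()) / 2)
    }
})

test_that("pattern tables agree with ground truth on noiseless data", {
    cfg <- simConfig(nGenes = 25, nStableGenes = 50, grid = humanLikeGrid(),
                     exact = TRUE, sizeFactorSigma = 0, profileSeed = 17)
    tce <- simulateTimeCourse(cfg)
    sc <- quietly(scaleUnitInterval(filterLowExpression(
        medianRatioNormalize(tce))))
    fits <- fitSegmentedModels(sc, fitOptions(minSegPoints = 3))
    pt <- patternTable(fits)
    gt <- groundTruth(tce)
    m <- merge(pt, gt, by = "gene", suffixes = c(".fit", ".true"))
    expect_true(all(m$label.fit == m$label.true))
    expect_true(all(m$onset.fit == m$onset.true))
})
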