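optsH <- fitOptions(minSegPoints = 3L)
optsM <- fitOptions(minSegPoints = 5L)

test_that("noiseless hinge data are inverted exactly at fixed breakpoints", {
    t <- gridTimes(humanLikeGrid())
    x <- hingeProfile(t, 0, 300, c(0.01, -0.01))
    fit <- fitFixedBreakpoints(x, t, 300, optsH)
    expect_lt(fit@rss, 1e-20)
    expect_equal(fit@segmentSlopes, c(0.01, -0.01), tolerance = 1e-10)
    expect_equal(fit@intercept, 0, tolerance = 1e-10)
    expect_gt(fit@adjR2, 0.999999)
})

test_that("a point exactly at a breakpoint belongs to the left segment", {
    t <- gridTimes(humanLikeGrid())
    x <- hingeProfile(t, 0, 300, c(0.01, -0.01))
    fit <- fitFixedBreakpoints(x, t, 300, optsH)
    expect_identical(fit@directions, c("up", "down"))
    expect_identical(fit@pointDirections[t == 300], "up")
    expect_identical(fit@pointDirections[t == 310], "down")
})

test_that("fixed-breakpoint RSS matches an independent normal-equations solve", {
    set.seed(7)
    t <- gridTimes(humanLikeGrid())
    for (b in list(100, c(150, 400), c(90, 300, 480))) {
        x <- runif(length(t))
        fit <- fitFixedBreakpoints(x, t, b, optsH)
        X <- cbind(1, t)
        for (bk in b) X <- cbind(X, pmax(t - bk, 0))
        beta <- solve(crossprod(X), crossprod(X, x))
        rssOracle <- sum((x - X %*% beta)^2)
        expect_equal(fit@rss, rssOracle, tolerance = 1e-10)
    }
})

test_that("fixed-breakpoint preconditions are enforced", {
    t <- gridTimes(humanLikeGrid())
    x <- runif(length(t))
    expect_error(fitFixedBreakpoints(x, t, 700, optsH), "interior")
    expect_error(fitFixedBreakpoints(x, t, c(100, 100), optsH),
                 "strictly increasing")
    expect_error(fitFixedBreakpoints(x, t, 10, optsM), "segment-length")
    expect_error(fitFixedBreakpoints(c(NA, x[-1]), t, 300, optsH), "missing")
})

test_that("BIC selects no breakpoints for an exact straight line", {
    t <- gridTimes(mouseLikeGrid())
    fit <- fitSegmented(0.001 * t + 0.1, t, optsM)
    expect_equal(fit@K, 0L)
    expect_equal(fit@segmentSlopes, 0.001, tolerance = 1e-8)
})

test_that("a noiseless V-shape recovers its vertex", {
    for (grid in list(mouseLikeGrid(), humanLikeGrid())) {
        t <- gridTimes(grid)
        opts <- if (gridInterval(grid) < 10) optsM else optsH
        x <- hingeProfile(t, 0, 300, c(1 / 300, -1 / 300))
        fit <- fitSegmented(x, t, opts)
        expect_equal(fit@K, 1L)
        expect_lt(abs(fit@breakpoints[1] - 300), gridInterval(grid) / 2)
    }
})

test_that("brute force at K = 0 equals the plain line fit", {
    t <- gridTimes(humanLikeGrid())
    set.seed(3)
    x <- runif(length(t))
    expect_equal(bruteForceFit(x, t, 0, optsH)@rss,
                 fitFixedBreakpoints(x, t, numeric(0), optsH)@rss)
})

test_that("brute force recovers the generating breakpoint on a short series", {
    t <- seq(0, 110, by = 10)   # 12 points
    x <- hingeProfile(t, 0, 60, c(0.01, -0.005))
    fit <- bruteForceFit(x, t, 1, optsH)
    expect_equal(fit@breakpoints, 60)
    expect_lt(fit@rss, 1e-20)
})

test_that("fit scores behave as BIC and adjusted R-squared must", {
    # perfect fit: adjusted R2 -> 1
    expect_gt(scoreFit(1e-14, 10, 61, 1)$adjR2, 0.999999)
    # equal RSS: the smaller K has the lower BIC
    expect_lt(scoreFit(1, 10, 61, 1)$bic, scoreFit(1, 10, 61, 2)$bic)
    # no better than the mean: adjusted R2 below zero
    expect_lt(scoreFit(10, 10, 61, 0)$adjR2, 0)
    # too few points: adjusted R2 undefined
    expect_true(is.na(scoreFit(1, 10, 5, 1)$adjR2))
})

test_that("segment direction p-values match a hand-rolled t-test", {
    set.seed(11)
    t <- gridTimes(humanLikeGrid())
    b <- c(200, 400)
    x <- hingeProfile(t, 0, b, c(0.004, 0, -0.003)) +
        rnorm(length(t), 0, 0.05)
    fit <- fitFixedBreakpoints(x, t, b, optsH)
    X <- cbind(1, t, pmax(t - b[1], 0), pmax(t - b[2], 0))
    cf <- solve(crossprod(X), crossprod(X, x))
    res <- x - X %*% cf
    df <- length(t) - 4L
    sigma2 <- sum(res^2) / df
    XtXinv <- solve(crossprod(X))
    for (j in 1:3) {
        cvec <- c(0, rep(1, j), rep(0, 3 - j))
        slope <- sum(cvec * cf)
        se <- sqrt(sigma2 * drop(t(cvec) %*% XtXinv %*% cvec))
        pOracle <- 2 * pt(-abs(slope / se), df)
        expect_equal(fit@segmentP[j], pOracle, tolerance = 1e-8)
    }
    # steep clean segments are called, exact zeros are "same"
    clean <- fitFixedBreakpoints(hingeProfile(t, 0, 300, c(0.01, 0)),
                                 t, 300, optsH)
    expect_identical(clean@directions[1], "up")
    expect_identical(clean@directions[2], "same")
    expect_lt(clean@segmentP[1], 1e-10)
})

test_that("relabelling directions at another alpha uses stored p-values", {
    t <- gridTimes(humanLikeGrid())
    set.seed(2)
    x <- hingeProfile(t, 0, 300, c(0.002, -0.001)) + rnorm(length(t), 0, 0.3)
    fit <- fitFixedBreakpoints(x, t, 300, optsH)
    strict <- classifySegmentDirections(fit, alpha = 1e-12)
    expect_true(all(strict == "same"))
    loose <- classifySegmentDirections(fit, alpha = 0.9999)
    expect_true(all(loose %in% c("up", "down")))
})

test_that("fitted curves are continuous at every breakpoint", {
    set.seed(5)
    t <- gridTimes(mouseLikeGrid())
    for (i in 1:5) {
        b0 <- sort(runif(2, 100, 500))
        x <- hingeProfile(t, 0.1, b0, c(0.004, -0.003, 0.002)) +
            rnorm(length(t), 0, 0.05)
        fit <- fitSegmented(x, t, optsM)
        expect_gte(fit@K, 1L)
        curve <- function(tt) {
            y <- fit@intercept + fit@segmentSlopes[1] * tt
            for (k in seq_len(fit@K))
                y <- y + (fit@segmentSlopes[k + 1] - fit@segmentSlopes[k]) *
                    pmax(tt - fit@breakpoints[k], 0)
            y
        }
        for (b in fit@breakpoints)
            expect_equal(curve(b - 1e-7), curve(b + 1e-7), tolerance = 1e-6)
    }
})

test_that("segment-length constraints bound the selected model", {
    set.seed(6)
    t <- gridTimes(humanLikeGrid())
    m <- optsH@minSegPoints
    for (i in 1:10) {
        x <- runif(length(t))
        fit <- fitSegmented(x, t, optsH)
        expect_lte(fit@K, length(t) %/% m - 1L)
        seg <- findInterval(t, fit@breakpoints, left.open = TRUE) + 1L
        expect_true(all(tabulate(seg, fit@K + 1L) >= m))
        if (fit@K > 0L) expect_gte(fit@breakpoints[1], t[m])
    }
    # a short profile can only be a straight line
    short <- fitSegmented(runif(5), seq(0, 40, 10), optsH)
    expect_equal(short@K, 0L)
})

test_that("refitting the fitted values reproduces the breakpoints", {
    set.seed(8)
    t <- gridTimes(mouseLikeGrid())
    x <- hingeProfile(t, 0.1, c(120, 360), c(0.004, -0.002, 0.001)) +
        rnorm(length(t), 0, 0.05)
    fit <- fitSegmented(x, t, optsM)
    refit <- fitSegmented(fit@fitted, t, optsM)
    expect_equal(refit@K, fit@K)
    expect_true(all(abs(refit@breakpoints - fit@breakpoints) <=
                        gridInterval(mouseLikeGrid()) / 2))
})

test_that("matrix-level fitting returns one fit per gene with ids", {
    cfg <- simConfig(nGenes = 4, nStableGenes = 2, grid = humanLikeGrid(),
                     dispersion = 0, seed = 3)
    tce <- quietly(scaleUnitInterval(filterLowExpression(
        medianRatioNormalize(simulateTimeCourse(cfg)))))
    fits <- fitSegmentedModels(tce, optsH)
    expect_equal(length(fits), nrow(tce))
    expect_identical(names(fits), rownames(tce))
    tab <- fitTable(fits)
    expect_equal(nrow(tab), nrow(tce))
    expect_true(all(c("gene", "K", "breakpoints", "adjR2", "dynamic") %in%
                        colnames(tab)))
    expect_s4_class(fits[[rownames(tce)[1]]], "SegmentedFit")
})
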