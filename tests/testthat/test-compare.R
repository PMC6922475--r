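test_that("ortholog maps are deduplicated and forced to 1:1", {
    om <- orthologMap(data.frame(a = c("a1", "a2"), b = c("b1", "b2")))
    expect_equal(nrow(om), 2L)
    expect_message(
        amb <- orthologMap(data.frame(a = c("a1", "a1", "a2"),
                                      b = c("b1", "b2", "b3"))),
        "many-to-many")
    expect_equal(amb$geneA, "a2")
    expect_error(orthologMap(data.frame(a = "a1", b = "b1")[0, ]),
                 "no ortholog pairs")
    path <- tempfile(fileext = ".tsv")
    writeLines(c("a1\tb1", "a2\tb2", "a2\tb9"), path)
    expect_message(om2 <- loadOrthologMap(path), "many-to-many")
    expect_equal(om2$geneA, "a1")
})

test_that("deltaM recovers constant shifts with the documented orientation", {
    a <- c(10, 25, 40, 55, 80)
    same <- deltaM(a, a)
    expect_equal(same$estimate, 0)
    expect_lte(same$ciLow, 0)
    expect_gte(same$ciHigh, 0)
    shifted <- deltaM(a, a + 100)
    expect_equal(shifted$estimate, 100, tolerance = 1e-9)
    # adding c to group B moves the estimate by +c (B-relative shift)
    expect_equal(deltaM(a, a + 130)$estimate, shifted$estimate + 30,
                 tolerance = 1e-9)
    # paired and unpaired agree when every pair shares one constant shift
    # (the paired CI is degenerate there: all differences are tied)
    p <- suppressWarnings(deltaM(a, a + 50, paired = TRUE))
    u <- deltaM(a, a + 50, paired = FALSE)
    expect_equal(p$estimate, u$estimate, tolerance = 1e-9)
    expect_warning(deltaM(c(5, 5, 5), c(5, 5, 5)), "degenerate")
})

test_that("deltaM matches the order-statistic Hodges-Lehmann oracle", {
    set.seed(42)
    for (i in 1:5) {
        # continuous values: no ties, so the exact-inversion path is used
        A <- runif(8 + i, 0, 100)
        B <- runif(12 + i, 0, 100)
        est <- deltaM(A, B, conf = 0.99)
        d <- sort(as.vector(outer(B, A, "-")))
        mB <- length(B); nA <- length(A)
        qu <- qwilcox(0.005, mB, nA)
        if (qu == 0) qu <- 1
        expect_equal(est$estimate, median(d), tolerance = 1e-6)
        expect_equal(est$ciLow, d[qu], tolerance = 1e-6)
        expect_equal(est$ciHigh, d[mB * nA - qu + 1], tolerance = 1e-6)
        # paired variant against the Walsh-average oracle
        x <- runif(10 + i, 0, 100)
        y <- x + rnorm(10 + i, 50, 30)
        estP <- deltaM(x, y, paired = TRUE, conf = 0.99)
        dd <- y - x
        n <- length(dd)
        w <- sort(as.vector(outer(dd, dd, "+")[
            lower.tri(diag(n), diag = TRUE)]) / 2)
        quP <- qsignrank(0.005, n)
        if (quP == 0) quP <- 1
        expect_equal(estP$estimate, median(w), tolerance = 1e-6)
        expect_equal(estP$ciLow, w[quP], tolerance = 1e-6)
        expect_equal(estP$ciHigh, w[length(w) - quP + 1], tolerance = 1e-6)
    }
})

test_that("deltaP matches the continuity-corrected closed form", {
    z <- qnorm(1 - 0.01 / 2)
    oracle <- function(k1, n1, k2, n2) {
        p1 <- k1 / n1; p2 <- k2 / n2
        corr <- min(0.5 * (1 / n1 + 1 / n2), abs(p1 - p2))
        w <- z * sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2) + corr
        100 * pmax(pmin(c(p1 - p2 - w, p1 - p2 + w), 1), -1)
    }
    dp <- deltaP(45, 50, 40, 50)
    expect_equal(dp$estimate, 10)
    expect_equal(c(dp$ciLow, dp$ciHigh), oracle(45, 50, 40, 50),
                 tolerance = 1e-10)
    zero <- deltaP(50, 100, 50, 100)
    expect_equal(zero$estimate, 0)
    expect_lt(zero$ciLow, 0)
    expect_gt(zero$ciHigh, 0)
    edge <- deltaP(0, 50, 50, 50)
    expect_equal(edge$estimate, -100)
    expect_gte(edge$ciLow, -100)
    expect_lte(edge$ciHigh, 100)
    expect_error(deltaP(5, 0, 1, 10), "positive")
    expect_error(deltaP(11, 10, 1, 10), "0 <= k <= n")
})

test_that("deltaS is a seeded, scale-equivariant ratio of median magnitudes", {
    b <- c(0.01, 0.02, 0.03, 0.05, 0.08)
    expect_equal(deltaS(b, b, B = 200)$estimate, 1)
    two <- deltaS(2 * b, b, B = 500, seed = 9)
    expect_equal(two$estimate, 2)
    expect_identical(two$ciLow, deltaS(2 * b, b, B = 500, seed = 9)$ciLow)
    # magnitudes: signs are ignored
    expect_equal(deltaS(-2 * b, b, B = 200)$estimate, 2)
    expect_error(deltaS(b, c(0, 0, 0)), "zero")
    expect_true(two$ciLow <= two$estimate && two$estimate <= two$ciHigh)
})

test_that("every-k-th subsampling matches the reduced-rate design", {
    cfg <- simConfig(nGenes = 3, nStableGenes = 0, grid = mouseLikeGrid(),
                     dispersion = 0, seed = 2)
    tce <- simulateTimeCourse(cfg)
    sub <- subsampleEveryK(tce, k = 3)
    expect_equal(ncol(sub), 49L)   # 145 samples -> every 3rd
    expect_equal(gridTimes(sub)[1:4], c(0, 12, 24, 36))
    expect_identical(SummarizedExperiment::assay(subsampleEveryK(tce, 1),
                                                 "counts"),
                     SummarizedExperiment::assay(tce, "counts"))
    expect_error(subsampleEveryK(tce, k = 500), "fewer than 2")
})

test_that("control overlap splits shared genes by first trend direction", {
    cfg <- simConfig(nGenes = 10, nStableGenes = 5, grid = humanLikeGrid(),
                     seed = 4)
    tce <- quietly(scaleUnitInterval(filterLowExpression(
        medianRatioNormalize(simulateTimeCourse(cfg)))))
    fits <- fitSegmentedModels(tce, fitOptions(minSegPoints = 3))
    ov <- controlOverlap(fits, fits)
    expect_equal(ov$nShared, length(dynamicGenes(fits)))
    expect_equal(ov$nSimilar, ov$nShared)
    expect_equal(ov$nOpposite, 0L)
    expect_identical(ov$breakpointsCondition, ov$breakpointsControl)
})

test_that("intron/exon window change follows the closed form", {
    t <- gridTimes(humanLikeGrid())
    n <- length(t)
    w <- 10L
    slope <- 0.5
    lin <- rbind(g1 = 100 + slope * t, g2 = rep(50, n))
    tce <- TimeCourseExperiment(lin, humanLikeGrid())
    out <- intronExonChange(tce, tce, window = w)
    expected <- slope * (mean(t[(n - w + 1):n]) - mean(t[1:w]))
    expect_equal(out$perGene$exonChange[out$perGene$gene == "g1"], expected)
    expect_equal(out$perGene$exonChange[out$perGene$gene == "g2"], 0)
    expect_equal(out$perGene$exonChange, out$perGene$intronChange)
    expect_equal(out$correlation, 1)
    short <- TimeCourseExperiment(lin[, 1:12], makeTimeGrid(10, 110))
    expect_error(intronExonChange(short, short, window = 10), "shorter")
})
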