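# Continuous piecewise-linear (hinge-basis) segmented regression with BIC
# selection of the breakpoint count under minimum-segment constraints.
#
# Model for K breakpoints b_1 < ... < b_K:
#   x(t) = beta0 + beta1 * t + sum_k gamma_k * (t - b_k)_+
# Segment k+1 has slope beta1 + gamma_1 + ... + gamma_k. A point exactly at a
# breakpoint belongs to the segment on its left (t <= b_k).

.hingeDesign <- function(t, b) {
    X <- cbind(1, t)
    for (bk in b) X <- cbind(X, pmax(t - bk, 0))
    X
}

.segIndex <- function(t, b) {
    if (length(b) == 0L) return(rep(1L, length(t)))
    idx <- rep(1L, length(t))
    for (bk in b) idx <- idx + (t > bk)
    idx
}

.rssAt <- function(x, t, b) {
    r <- .lm.fit(.hingeDesign(t, b), x)$residuals
    sum(r * r)
}

# Feasibility in index space: i_k = #(t <= b_k) must satisfy
# i_1 >= m, i_{k+1} >= i_k + m, i_K <= n - m.
.idxFeasible <- function(idx, n, m) {
    K <- length(idx)
    if (K == 0L) return(TRUE)
    all(idx >= m + (seq_len(K) - 1L) * m) &&
        all(idx <= n - m * (K - seq_len(K) + 1L)) &&
        (K == 1L || all(diff(idx) >= m))
}

# Project an index vector into the feasible region (left then right pass).
.projectIdx <- function(idx, n, m) {
    K <- length(idx)
    if (K == 0L) return(idx)
    idx <- sort(idx)
    for (k in seq_len(K))
        idx[k] <- max(idx[k], if (k == 1L) m else idx[k - 1L] + m)
    for (k in rev(seq_len(K)))
        idx[k] <- min(idx[k], if (k == K) n - m else idx[k + 1L] - m)
    if (!.idxFeasible(idx, n, m)) return(NULL)
    idx
}

# Feasibility of continuous breakpoints; snaps infeasible ones to grid times.
.projectB <- function(t, b, m) {
    n <- length(t)
    b <- sort(b)
    idx <- findInterval(b, t)
    if (.idxFeasible(idx, n, m) && all(b > t[1L]) && all(b < t[n]))
        return(b)
    idx <- .projectIdx(idx, n, m)
    if (is.null(idx)) return(NULL)
    t[idx]
}

# One Muggeo-style linearized update pass: augment the hinge design with
# V_k = -(t > b_k) columns; the fitted ratio coef(V_k)/coef(U_k) estimates the
# shift of b_k. Damped and projected to respect segment-length constraints.
.muggeoRefine <- function(x, t, b0, m, maxit = 30L, tol = 0.02) {
    b <- .projectB(t, b0, m)
    if (is.null(b)) return(NULL)
    best <- list(b = b, rss = .rssAt(x, t, b))
    K <- length(b)
    for (it in seq_len(maxit)) {
        U <- vapply(b, function(bk) pmax(t - bk, 0), numeric(length(t)))
        V <- vapply(b, function(bk) -as.numeric(t > bk), numeric(length(t)))
        cf <- lm.fit(cbind(1, t, U, V), x)$coefficients
        gU <- cf[2L + seq_len(K)]
        gV <- cf[2L + K + seq_len(K)]
        delta <- ifelse(is.na(gU) | is.na(gV) | abs(gU) < 1e-12, 0, gV / gU)
        if (all(abs(delta) < tol)) break
        h <- 1
        improved <- FALSE
        for (half in 1:5) {
            cand <- .projectB(t, b + h * delta, m)
            if (!is.null(cand)) {
                rss <- .rssAt(x, t, cand)
                if (rss <= best$rss + 1e-12) {
                    if (rss < best$rss) best <- list(b = cand, rss = rss)
                    b <- cand
                    improved <- TRUE
                    break
                }
            }
            h <- h / 2
        }
        if (!improved) break
    }
    best
}

# Discrete coordinate descent over observed candidate times in index space.
.coordDescent <- function(x, t, idx, m, sweeps = 3L) {
    n <- length(t)
    K <- length(idx)
    best <- .rssAt(x, t, t[idx])
    for (s in seq_len(sweeps)) {
        changed <- FALSE
        for (k in seq_len(K)) {
            lo <- if (k == 1L) m else idx[k - 1L] + m
            hi <- if (k == K) n - m else idx[k + 1L] - m
            if (lo > hi) next
            cand <- lo:hi
            vals <- vapply(cand, function(i) {
                ii <- idx
                ii[k] <- i
                .rssAt(x, t, t[ii])
            }, numeric(1))
            j <- which.min(vals)
            if (vals[j] < best - 1e-12) {
                idx[k] <- cand[j]
                best <- vals[j]
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    list(idx = idx, rss = best)
}

# Enumerate feasible index combinations for exhaustive search.
.enumIdx <- function(n, K, m, budget = 2e5) {
    out <- list()
    count <- 0L
    rec <- function(prefix, k) {
        lo <- if (k == 1L) m else prefix[k - 1L] + m
        hi <- n - m * (K - k + 1L)
        if (lo > hi) return()
        for (i in lo:hi) {
            count <<- count + 1L
            if (count > budget)
                stop("enumeration budget exceeded for brute-force search")
            if (k == K) out[[length(out) + 1L]] <<- c(prefix, i)
            else rec(c(prefix, i), k + 1L)
        }
    }
    if (K >= 1L) rec(integer(0), 1L)
    out
}

# Best breakpoints for a fixed K. Deterministic: exhaustive over observed
# interior times when K <= 2 and n <= 40, otherwise quantile-spaced starts
# refined by Muggeo iterations, then coordinate descent over the candidate
# grid, then a final continuous refinement.
.optimizeBreakpoints <- function(x, t, K, m, exhaustive = NULL) {
    n <- length(t)
    if (K == 0L)
        return(list(b = numeric(0), rss = .rssAt(x, t, numeric(0))))
    if (is.null(exhaustive)) exhaustive <- (K <= 2L && n <= 40L)
    if (exhaustive) {
        combos <- .enumIdx(n, K, m)
        if (length(combos) == 0L) return(NULL)
        rss <- vapply(combos, function(ii) .rssAt(x, t, t[ii]), numeric(1))
        j <- which.min(rss)   # ties resolve to the earliest combination
        best <- list(b = t[combos[[j]]], rss = rss[j])
        ref <- .muggeoRefine(x, t, best$b, m)
        if (!is.null(ref) && ref$rss < best$rss - 1e-12) best <- ref
        return(best)
    }
    fracs <- list(seq_len(K) / (K + 1), seq_len(K) / (K + 2),
                  (seq_len(K) + 1) / (K + 2))
    best <- NULL
    for (fr in fracs) {
        idx <- .projectIdx(pmax(1L, round(fr * n)), n, m)
        if (is.null(idx)) next
        sol <- .muggeoRefine(x, t, t[idx], m)
        if (!is.null(sol) && (is.null(best) || sol$rss < best$rss))
            best <- sol
    }
    if (is.null(best)) return(NULL)
    idx <- .projectIdx(findInterval(best$b, t), length(t), m)
    if (!is.null(idx)) {
        cd <- .coordDescent(x, t, idx, m)
        if (cd$rss < best$rss - 1e-12)
            best <- list(b = t[cd$idx], rss = cd$rss)
        ref <- .muggeoRefine(x, t, if (cd$rss < best$rss + 1e-12)
            t[cd$idx] else best$b, m)
        if (!is.null(ref) && ref$rss < best$rss - 1e-12) best <- ref
    }
    best
}

#' Fit options constructor
#'
#' @param maxBreakpoints largest breakpoint count considered (default 5).
#' @param minSegPoints minimum observed time points per segment; use 5 on
#'   4-minute grids and 3 on 10-minute or week-long grids so every segment
#'   spans at least 20 or 30 minutes.
#' @param directionAlpha p-value threshold for calling a segment slope
#'   "up"/"down" rather than "same" (default 0.2).
#' @param r2Threshold adjusted R-squared gate defining dynamic genes
#'   (default 0.2; raise to 0.5 for week-long series).
#' @return A \linkS4class{FitOptions}.
#' @export
fitOptions <- function(maxBreakpoints = 5L, minSegPoints = 5L,
                       directionAlpha = 0.2, r2Threshold = 0.2) {
    new("FitOptions", maxBreakpoints = as.integer(maxBreakpoints),
        minSegPoints = as.integer(minSegPoints),
        directionAlpha = directionAlpha, r2Threshold = r2Threshold)
}

#' Fit-quality scores for a segmented model
#'
#' BIC is computed as \code{n*log(RSS/n) + p*log(n)} and adjusted R-squared as
#' \code{1 - (1 - R2)*(n - 1)/(n - p - 1)}, both with \code{p = 2 + 2K}
#' parameters (intercept, base slope, K hinge coefficients and K estimated
#' breakpoint locations).
#'
#' @param rss residual sum of squares.
#' @param tss total sum of squares of the profile about its mean.
#' @param n number of observations.
#' @param K number of breakpoints.
#' @return List with \code{bic} and \code{adjR2} (\code{NA} when
#'   \code{n <= p + 1}).
#' @export
scoreFit <- function(rss, tss, n, K) {
    p <- 2 + 2 * K
    bic <- n * log(max(rss, 1e-12) / n) + p * log(n)
    adjR2 <- if (n <= p + 1) NA_real_ else {
        r2 <- 1 - rss / tss
        1 - (1 - r2) * (n - 1) / (n - p - 1)
    }
    list(bic = bic, adjR2 = adjR2)
}

# Per-segment slope inference from the hinge-basis OLS covariance.
# Slope of segment j is beta1 + sum_{k<j} gamma_k, a linear contrast of the
# regression coefficients; its t-test uses df = n - (K + 2).
.segmentInference <- function(X, x, K) {
    n <- nrow(X)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        stop("singular segmented design (degenerate breakpoints)")
    cf <- qr.coef(qrX, x)
    res <- x - X %*% cf
    rss <- sum(res * res)
    df <- n - (K + 2L)
    sigma2 <- if (df > 0L) rss / df else 0
    XtXinv <- chol2inv(qr.R(qrX))
    slopes <- cumsum(cf[-1L])          # beta1, beta1+g1, ...
    pvals <- numeric(K + 1L)
    for (j in seq_len(K + 1L)) {
        cvec <- c(0, rep(1, j), rep(0, K + 1L - j))
        se <- sqrt(max(sigma2 * drop(t(cvec) %*% XtXinv %*% cvec), 0))
        if (se < 1e-14) {
            pvals[j] <- if (abs(slopes[j]) < 1e-14) 1 else 0
        } else {
            pvals[j] <- 2 * stats::pt(-abs(slopes[j] / se), df)
        }
    }
    list(coef = cf, fitted = drop(X %*% cf), rss = rss,
         slopes = unname(slopes), pvals = pvals)
}

#' Label segment directions by a slope t-test
#'
#' Each segment is labelled \code{"up"} or \code{"down"} by the sign of its
#' fitted slope when the two-sided t-test p-value (from the full segmented
#' design's OLS covariance) is below \code{alpha}, and \code{"same"}
#' otherwise.
#'
#' @param fit a \linkS4class{SegmentedFit}.
#' @param alpha per-segment p-value threshold (default 0.2).
#' @return Character vector of per-segment directions.
#' @export
classifySegmentDirections <- function(fit, alpha = 0.2) {
    ifelse(fit@segmentP >= alpha, "same",
           ifelse(fit@segmentSlopes > 0, "up", "down"))
}

# Assemble a SegmentedFit at fixed breakpoints (shared by all fitters).
.buildFit <- function(x, t, b, alpha, gene = "") {
    K <- length(b)
    inf <- .segmentInference(.hingeDesign(t, b), x, K)
    tss <- sum((x - mean(x))^2)
    sc <- scoreFit(inf$rss, tss, length(x), K)
    fit <- new("SegmentedFit", gene = gene, K = as.integer(K),
               breakpoints = as.numeric(b), intercept = unname(inf$coef[1L]),
               segmentSlopes = inf$slopes, fitted = inf$fitted,
               rss = inf$rss, bic = sc$bic, adjR2 = sc$adjR2,
               segmentP = inf$pvals,
               directions = rep("same", K + 1L),
               pointDirections = character(length(t)),
               times = as.numeric(t))
    fit@directions <- classifySegmentDirections(fit, alpha)
    fit@pointDirections <- fit@directions[.segIndex(t, b)]
    fit
}

.gridTimesOf <- function(grid) {
    if (is(grid, "TimeGrid")) grid@times else as.numeric(grid)
}

#' Segmented least squares at fixed breakpoints
#'
#' Solves the continuous hinge-basis model at user-supplied breakpoint
#' times and scores the fit. Breakpoints must be interior to the grid,
#' strictly increasing, and leave at least \code{minSegPoints} observed times
#' in every segment (a point at a breakpoint counts to the left segment).
#'
#' @param x numeric scaled expression profile.
#' @param grid a \linkS4class{TimeGrid} or numeric vector of times.
#' @param breakpoints numeric breakpoint times (possibly empty).
#' @param opts a \linkS4class{FitOptions}.
#' @param gene optional gene identifier stored in the fit.
#' @return A \linkS4class{SegmentedFit}.
#' @examples
#' t <- gridTimes(humanLikeGrid())
#' x <- 0.002 * pmin(t, 300) - 0.001 * pmax(t - 300, 0)
#' fit <- fitFixedBreakpoints(x, t, 300, fitOptions(minSegPoints = 3))
#' fit@segmentSlopes
#' @export
fitFixedBreakpoints <- function(x, grid, breakpoints = numeric(0),
                                opts = fitOptions(), gene = "") {
    t <- .gridTimesOf(grid)
    x <- as.numeric(x)
    if (length(x) != length(t))
        stop("profile length must equal the number of grid times")
    if (anyNA(x)) stop("profile contains missing values")
    b <- sort(as.numeric(breakpoints))
    if (length(b)) {
        if (any(b <= t[1L]) || any(b >= t[length(t)]))
            stop("breakpoints must be interior to the time grid")
        if (any(diff(b) <= 0))
            stop("breakpoints must be strictly increasing")
        if (!.idxFeasible(findInterval(b, t), length(t), opts@minSegPoints))
            stop("segment-length violation: every segment needs at least ",
                 opts@minSegPoints, " observed time points")
    }
    .buildFit(x, t, b, opts@directionAlpha, gene)
}

#' Fit the best segmented model by BIC
#'
#' For each breakpoint count K = 0..\code{maxBreakpoints} (capped by what the
#' minimum-segment rule allows), optimizes breakpoint locations and retains
#' the model with the lowest BIC (ties go to the smaller K). The breakpoint
#' search is fully deterministic: exhaustive over observed interior times for
#' K <= 2 on short series, otherwise quantile-spaced starts refined by
#' damped linearized (Muggeo-type) updates plus coordinate descent over the
#' observed-time candidate grid.
#'
#' @inheritParams fitFixedBreakpoints
#' @return A \linkS4class{SegmentedFit} for the BIC-selected model.
#' @examples
#' t <- gridTimes(humanLikeGrid())
#' x <- 0.004 * pmin(t, 240) - 0.003 * pmax(t - 240, 0)
#' fit <- fitSegmented(x, t, fitOptions(minSegPoints = 3))
#' c(fit@K, fit@breakpoints)
#' @export
fitSegmented <- function(x, grid, opts = fitOptions(), gene = "") {
    t <- .gridTimesOf(grid)
    x <- as.numeric(x)
    if (length(x) != length(t))
        stop("profile length must equal the number of grid times")
    if (anyNA(x) || any(!is.finite(x)))
        stop("profile contains missing or non-finite values")
    n <- length(t)
    m <- opts@minSegPoints
    kMax <- min(opts@maxBreakpoints, max(0L, n %/% m - 1L))
    sols <- vector("list", kMax + 1L)
    bics <- rep(Inf, kMax + 1L)
    for (K in 0:kMax) {
        sol <- .optimizeBreakpoints(x, t, K, m)
        if (is.null(sol)) next
        sols[[K + 1L]] <- sol
        bics[K + 1L] <- scoreFit(sol$rss, 1, n, K)$bic
    }
    bestK <- 0L
    for (K in 0:kMax) {
        if (bics[K + 1L] < bics[bestK + 1L] - 1e-9) bestK <- K
    }
    .buildFit(x, t, sols[[bestK + 1L]]$b, opts@directionAlpha, gene)
}

#' Exhaustive-search oracle fit
#'
#' Finds the global residual-sum-of-squares minimum over all breakpoint
#' placements restricted to observed interior times that respect the
#' minimum-segment rule. Intended as a verification oracle for small
#' problems; errors when the enumeration budget is exceeded.
#'
#' @inheritParams fitFixedBreakpoints
#' @param K the (fixed) number of breakpoints to place.
#' @param refine if \code{TRUE}, follow the grid optimum with a continuous
#'   refinement; \code{FALSE} keeps breakpoints on observed times.
#' @return A \linkS4class{SegmentedFit}.
#' @export
bruteForceFit <- function(x, grid, K, opts = fitOptions(), gene = "",
                          refine = FALSE) {
    t <- .gridTimesOf(grid)
    x <- as.numeric(x)
    K <- as.integer(K)
    m <- opts@minSegPoints
    if (K == 0L) return(.buildFit(x, t, numeric(0), opts@directionAlpha, gene))
    combos <- .enumIdx(length(t), K, m)
    if (length(combos) == 0L)
        stop("no feasible breakpoint placement for K = ", K)
    rss <- vapply(combos, function(ii) .rssAt(x, t, t[ii]), numeric(1))
    j <- which.min(rss)
    b <- t[combos[[j]]]
    if (refine) {
        ref <- .muggeoRefine(x, t, b, m)
        if (!is.null(ref) && ref$rss < rss[j] - 1e-12) b <- ref$b
    }
    .buildFit(x, t, b, opts@directionAlpha, gene)
}

#' Fit segmented models to every gene of an experiment
#'
#' Runs [fitSegmented()] on each row of the \code{"scaled"} assay.
#'
#' @param tce a \linkS4class{TimeCourseExperiment} carrying a scaled assay
#'   (see [scaleUnitInterval()]).
#' @param opts a \linkS4class{FitOptions}.
#' @param assayName assay to fit (default \code{"scaled"}).
#' @param verbose report progress every 100 genes.
#' @return A \linkS4class{TrendFitSet}.
#' @export
fitSegmentedModels <- function(tce, opts = fitOptions(),
                               assayName = "scaled", verbose = FALSE) {
    if (!assayName %in% assayNames(tce))
        .stageError("fit", sprintf("assay '%s' not found; run preprocessing first",
                                   assayName))
    xMat <- assay(tce, assayName)
    if (nrow(xMat) == 0L)
        .stageError("fit", "no genes to fit")
    grid <- timeGrid(tce)
    ids <- rownames(tce)
    fits <- vector("list", nrow(xMat))
    for (i in seq_len(nrow(xMat))) {
        fits[[i]] <- fitSegmented(xMat[i, ], grid, opts, gene = ids[i])
        if (verbose && i %% 100L == 0L)
            message(sprintf("fitSegmentedModels: %d / %d genes", i, nrow(xMat)))
    }
    new("TrendFitSet", fits = fits, options = opts, grid = grid,
        geneIds = ids)
}

#' Tabulate a set of segmented fits
#'
#' One row per gene: breakpoint count, breakpoint times, segment slopes,
#' directions and p-values (comma-joined), adjusted R-squared, BIC, the
#' dynamic call at the configured gate, and the per-time-point trend
#' direction string.
#'
#' @param x a \linkS4class{TrendFitSet}.
#' @param ... unused.
#' @return A \code{data.frame}.
#' @name fitTable
NULL

#' @rdname fitTable
#' @export
setMethod("fitTable", "TrendFitSet", function(x, ...) {
    gate <- x@options@r2Threshold
    rows <- lapply(x@fits, function(f) {
        data.frame(
            gene = f@gene, K = f@K,
            breakpoints = .commaJoin(f@breakpoints),
            segmentSlopes = .commaJoin(f@segmentSlopes),
            segmentDirections = paste(f@directions, collapse = ","),
            segmentP = .commaJoin(f@segmentP),
            adjR2 = f@adjR2, bic = f@bic, rss = f@rss,
            dynamic = !is.na(f@adjR2) && f@adjR2 > gate,
            pointDirections = paste(f@pointDirections, collapse = ","),
            stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
})

#' Genes passing the adjusted R-squared gate
#'
#' @param x a \linkS4class{TrendFitSet}.
#' @param gate adjusted R-squared threshold; defaults to the fit options'.
#' @param ... unused.
#' @return Character vector of dynamic gene ids.
#' @name dynamicGenes
NULL

#' @rdname dynamicGenes
#' @export
setMethod("dynamicGenes", "TrendFitSet", function(x, gate = NULL, ...) {
    if (is.null(gate)) gate <- x@options@r2Threshold
    ok <- vapply(x@fits, function(f) !is.na(f@adjR2) && f@adjR2 > gate,
                 logical(1))
    x@geneIds[ok]
})

setMethod("show", "SegmentedFit", function(object) {
    cat(sprintf("SegmentedFit '%s': K = %d, adjR2 = %.3f, BIC = %.1f\n",
                object@gene, object@K, object@adjR2, object@bic))
    if (object@K > 0L)
        cat("  breakpoints:", paste(round(object@breakpoints, 1),
                                    collapse = ", "), "min\n")
    cat("  directions: ", paste(object@directions, collapse = "-"), "\n")
})

setMethod("show", "TrendFitSet", function(object) {
    dyn <- length(dynamicGenes(object))
    cat(sprintf("TrendFitSet: %d genes (%d dynamic at adjR2 > %g), %d times\n",
                length(object@fits), dyn, object@options@r2Threshold,
                length(object@grid@times)))
})

setMethod("length", "TrendFitSet", function(x) length(x@fits))

#' @export
setMethod("[[", "TrendFitSet", function(x, i) {
    if (is.character(i)) i <- match(i, x@geneIds)
    x@fits[[i]]
})

#' @export
setMethod("names", "TrendFitSet", function(x) x@geneIds)
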