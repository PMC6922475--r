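# shared fixtures built in code

# A noiseless hinge profile on a grid: baseline + slopes around breakpoints.
hingeProfile <- function(times, baseline, breakpoints, slopes) {
    y <- baseline + slopes[1L] * times
    for (k in seq_along(breakpoints))
        y <- y + (slopes[k + 1L] - slopes[k]) * pmax(times - breakpoints[k], 0)
    y
}

# Tiny count experiment with explicit values.
tinyCounts <- function(m, interval = 10) {
    grid <- makeTimeGrid(interval, interval * (ncol(m) - 1L))
    if (is.null(rownames(m)))
        rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
    TimeCourseExperiment(m, grid)
}

quietly <- function(expr) suppressMessages(expr)
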