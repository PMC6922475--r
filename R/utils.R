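# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    code
}

# Derive a child seed from a top-level seed and an integer stage tag.
# Kept inside [1, 2^31 - 2] so it is always a valid R integer seed.
.deriveSeed <- function(seed, tag) {
    s <- (as.double(seed) %% 2147483647) + 1
    v <- (s * 48271 + as.double(tag) * 9973) %% 2147483647
    as.integer(v) + 1L
}

.gcdPair <- function(a, b) {
    while (b > 1e-9) {
        r <- a %% b
        a <- b
        b <- r
    }
    a
}

# Greatest common divisor of a set of (near-integer) spacings.
.gcdAll <- function(x) Reduce(.gcdPair, x)

.stageError <- function(stage, msg) {
    stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}

.commaJoin <- function(x, digits = 6) {
    if (length(x) == 0L) return("")
    paste(formatC(x, digits = digits, format = "g"), collapse = ",")
}

.commaSplit <- function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]])
}
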