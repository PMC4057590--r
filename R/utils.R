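# internal helpers shared across modules

# round half away from zero (all quantities here are non-negative)
roundHalfUp <- function(x) floor(x + 0.5)

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("seed must be a single integer")
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# cumulative trapezoidal integral of y over x, same length as x
cumTrapz <- function(x, y) {
    n <- length(x)
    stopifnot(length(y) == n)
    if (n == 1L) return(0)
    c(0, cumsum(diff(x) * (y[-n] + y[-1]) / 2))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assertMask <- function(m, what = "mask") {
    if (!is.matrix(m) || !is.logical(m))
        stopf("%s must be a logical matrix", what)
    invisible(m)
}
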