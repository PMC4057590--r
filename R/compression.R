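#' Log-compress echo power to 8-bit display levels
#'
#' Forward model of the scanner display mapping: echo power \code{E} (a.u.)
#' is mapped onto \code{levels} integer display values over a dynamic range
#' of \code{drDb} decibels ending at full scale \code{eRef},
#' \deqn{D = \mathrm{round}\left((L-1)\,
#'   \mathrm{clamp}\!\left(1 + \frac{10\log_{10}(E/e_{ref})}{dr},\,0,\,1\right)\right).}
#' Zero power maps to level 0 (the logarithm is clamped, never an error);
#' rounding is half-away-from-zero so that the round-trip error bound of
#' [linearize()] is exact.
#'
#' @param E numeric vector, matrix or array of echo powers, all >= 0.
#' @param law a [CompressionLaw-class].
#' @return Integer display levels with the shape of \code{E}.
#' @examples
#' law <- compressionLaw(drDb = 7, eRef = 100)
#' logCompress(c(100, 100 * 10^(-0.35), 100 * 10^(-0.7)), law)
#' @seealso [linearize()]
#' @export
logCompress <- function(E, law = compressionLaw()) {
    stopifnot(is(law, "CompressionLaw"))
    if (any(E < 0, na.rm = TRUE))
        stopf("echo power must be non-negative")
    L <- law@levels
    x <- 1 + 10 * log10(E / law@eRef) / law@drDb
    x[E == 0] <- 0          # log of zero maps below range
    x <- pmin(pmax(x, 0), 1)
    D <- roundHalfUp((L - 1L) * x)
    storage.mode(D) <- "integer"
    D
}

#' Linearize 8-bit display levels back to echo power
#'
#' Inversion of the display log-compression ("linearization"), recovering
#' values proportional to echo power:
#' \deqn{E = e_{ref}\, 10^{\,dr\,(D/(L-1) - 1)/10}.}
#' After linearization, region means are area-weighted means of region
#' powers, the property that justifies averaging echo power rather than
#' display values.
#'
#' @param D display levels in \code{[0, levels-1]} (vector, matrix or array).
#' @param law a [CompressionLaw-class].
#' @return Echo power (a.u.) with the shape of \code{D}.
#' @examples
#' law <- compressionLaw(drDb = 7, eRef = 100)
#' linearize(c(0L, 255L), law)  # bottom of range, full scale
#' @seealso [logCompress()]
#' @export
linearize <- function(D, law = compressionLaw()) {
    stopifnot(is(law, "CompressionLaw"))
    L <- law@levels
    if (any(D < 0 | D > L - 1L, na.rm = TRUE))
        stopf("display values must lie in [0, %d]", L - 1L)
    law@eRef * 10^(law@drDb * (D / (L - 1L) - 1) / 10)
}

#' Linearization lookup table
#'
#' Echo power for every display level, used to vectorize per-frame ROI
#' statistics over 8-bit cine stacks.
#'
#' @param law a [CompressionLaw-class].
#' @return Numeric vector of length \code{levels}; entry \code{d + 1} is
#'   the linearized power of display level \code{d}.
#' @keywords internal
linearizeLUT <- function(law) linearize(seq_len(law@levels) - 1L, law)

#' Worst-case round-trip error of the compression law
#'
#' Upper bound on the relative error of
#' \code{linearize(logCompress(E))} for in-range \code{E}: half a display
#' level, i.e. \code{10^(drDb / (10 * 2 * (levels-1))) - 1} (about 0.32%
#' at 7 dB and 256 levels).
#'
#' @param law a [CompressionLaw-class].
#' @return The relative error bound (dimensionless).
#' @export
roundTripTolerance <- function(law = compressionLaw()) {
    10^(law@drDb / (10 * 2 * (law@levels - 1L))) - 1
}
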