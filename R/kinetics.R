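#' Circulating microbubble concentration over an exam
#'
#' Closed-form bolus model: a gamma-variate first pass
#' \deqn{g(t) = A\,(t/t_p)^{\alpha} e^{\alpha(1 - t/t_p)},}
#' peaking at \code{bolusPeakTime} with value \code{bolusAmplitude}, plus a
#' recirculating pool \eqn{A\,f_{rec}(1 - e^{-t/\tau_{rec}})e^{-t/\tau_w}}
#' that equilibrates with time constant \code{recircTau} and clears with
#' \code{washoutTau}. When the exam includes a destructive flash, in-plane
#' bubbles are zeroed over the flash interval and afterwards relax back to
#' the unflashed trajectory with time constant \code{replenishTau}
#' (replenishment from out-of-plane blood).
#'
#' @param params a [KineticParams-class].
#' @param times strictly increasing numeric vector of seconds after
#'   injection, starting at 0 or later.
#' @param applyFlash if \code{FALSE}, return the unflashed trajectory
#'   (useful as the reference curve in destruction-replenishment checks).
#' @return Numeric vector of circulating concentration, a.u., same length
#'   as \code{times}.
#' @examples
#' kp <- kineticParams()
#' t <- seq(0, 385, by = 0.1)
#' c_t <- simulateCirculating(kp, t)
#' t[which.max(c_t)]  # near the bolus peak time
#' @seealso [simulateBound()], [renderCine()]
#' @export
simulateCirculating <- function(params, times, applyFlash = TRUE) {
    stopifnot(is(params, "KineticParams"))
    validObject(params)
    if (length(times) == 0L || any(times < 0) ||
        is.unsorted(times, strictly = TRUE))
        stopf("times must be strictly increasing and non-negative")
    A <- params@bolusAmplitude
    tp <- params@bolusPeakTime
    a <- params@bolusShape
    u <- times / tp
    g <- ifelse(times > 0, A * u^a * exp(a * (1 - u)), 0)
    rec <- A * params@recircFraction * (1 - exp(-times / params@recircTau)) *
        exp(-times / params@washoutTau)
    curve <- g + rec
    if (applyFlash) {
        onset <- params@flashOnset
        end <- onset + params@flashDuration
        curve[times >= onset & times < end] <- 0
        post <- times >= end
        curve[post] <- curve[post] *
            (1 - exp(-(times[post] - end) / params@replenishTau))
    }
    curve
}

#' Receptor-bound microbubble signal over an exam
#'
#' The bound pool accumulates in proportion to receptor density and to the
#' circulating exposure,
#' \deqn{B(t) = \rho\, k_{on} \int_0^t C(s)\, ds}
#' (cumulative trapezoid over the sampled curve), until the destructive
#' flash zeroes it; within the remaining seconds of the exam re-binding is
#' negligible and the bound pool is not re-formed.
#'
#' @param circulating numeric vector from [simulateCirculating()] (the
#'   pre-flash portion is what matters; flashed and unflashed curves agree
#'   there).
#' @param times the time grid of \code{circulating}, seconds.
#' @param rho receptor density, dimensionless >= 0.
#' @param kOn binding rate constant, 1/(a.u. s).
#' @param flash numeric of length 0 (no flash) or 2 (onset, end), seconds.
#' @return Numeric vector of bound signal, a.u.
#' @examples
#' kp <- kineticParams()
#' t <- seq(0, 385, by = 0.1)
#' b <- simulateBound(simulateCirculating(kp, t, applyFlash = FALSE), t,
#'     rho = 1, kOn = 0.03, flash = c(360, 361))
#' @export
simulateBound <- function(circulating, times, rho, kOn,
        flash = numeric()) {
    if (length(rho) != 1L || is.na(rho) || rho < 0)
        stopf("rho must be a single non-negative number")
    if (length(kOn) != 1L || is.na(kOn) || kOn < 0)
        stopf("kOn must be a single non-negative number")
    if (length(circulating) != length(times))
        stopf("circulating and times must have equal length")
    bound <- rho * kOn * cumTrapz(times, circulating)
    if (length(flash) == 2L)
        bound[times >= flash[1]] <- 0
    bound
}
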