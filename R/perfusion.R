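#' Peak arterial enhancement frame
#'
#' Index of the frame with maximal ROI echo power within the search window
#' (by default the first 30 seconds, the arterial-phase clip); ties go to
#' the earliest frame.
#'
#' @param tic a [TimeIntensityCurve-class].
#' @param searchWindow numeric \code{c(start, end)} in seconds, half-open.
#' @return Integer frame index into the curve.
#' @examples
#' ph <- tumorPhantom(dim = c(32, 32))
#' cine <- renderCine(ph, kineticParams(), seed = 1)
#' tic <- roiTIC(cine, tumorMask(ph))
#' frameTimes(tic)[peakEnhancementFrame(tic)]
#' @export
peakEnhancementFrame <- function(tic, searchWindow = c(0, 30)) {
    stopifnot(is(tic, "TimeIntensityCurve"))
    inWin <- tic@times >= searchWindow[1] & tic@times < searchWindow[2]
    if (!any(inWin))
        stopf("search window [%g, %g) contains no frames",
            searchWindow[1], searchWindow[2])
    idx <- which(inWin)
    idx[which.max(tic@values[idx])]
}

#' Fraction of non-enhanced tumour area
#'
#' On a linearized peak-enhancement frame, the percentage of ROI pixels
#' whose echo power falls below \code{thresholdFactor} times the
#' background level (median linearized power outside the ROI). This
#' operationalizes the visual scoring of non-perfused area; the threshold
#' is configurable because the original scoring was by eye.
#'
#' @param frame numeric matrix of linearized echo power (a.u.).
#' @param roi non-empty logical matrix.
#' @param thresholdFactor multiple of the background median below which a
#'   pixel counts as non-enhanced (default 2).
#' @return Raw percentage in \code{[0, 100]}.
#' @examples
#' ph <- tumorPhantom(dim = c(48, 48), necroticFraction = 0.3)
#' cine <- renderCine(ph, kineticParams(), seed = 1)
#' tic <- roiTIC(cine, tumorMask(ph))
#' i <- peakEnhancementFrame(tic)
#' E <- linearize(frames(cine)[, , i], compressionLawOf(cine))
#' nonEnhancedFraction(E, tumorMask(ph))
#' @seealso [quantizeStep10()], [consensusReading()]
#' @export
nonEnhancedFraction <- function(frame, roi, thresholdFactor = 2) {
    if (!is.matrix(frame) || !is.numeric(frame))
        stopf("frame must be a numeric matrix of linearized power")
    assertMask(roi, "roi")
    if (!identical(dim(roi), dim(frame)))
        stopf("roi dimensions must match the frame")
    if (!any(roi)) stopf("roi is empty")
    if (all(roi)) stopf("no background pixels outside the roi")
    bg <- stats::median(frame[!roi])
    if (!is.finite(bg) || bg <= 0)
        stopf("degenerate background outside the roi (median %g)", bg)
    100 * mean(frame[roi] < thresholdFactor * bg)
}

#' Quantize a percentage to the 10% step scale
#'
#' Nearest multiple of 10 within \code{[0, 100]}; halves round up.
#'
#' @param raw percentage in \code{[0, 100]}.
#' @return Multiple of 10.
#' @examples
#' quantizeStep10(c(23, 25, 0))
#' @export
quantizeStep10 <- function(raw) {
    if (any(!is.finite(raw)) || any(raw < 0 | raw > 100))
        stopf("raw percentage must lie in [0, 100]")
    10 * roundHalfUp(raw / 10)
}

#' A single reader's non-enhanced-area reading
#'
#' @param raw raw percentage in \code{[0, 100]}.
#' @param readerId label of the reader.
#' @return A list with components \code{raw}, \code{quantized},
#'   \code{readerId}.
#' @examples
#' perfusionReading(23, "A")
#' @export
perfusionReading <- function(raw, readerId = "A") {
    list(raw = as.numeric(raw), quantized = quantizeStep10(raw),
        readerId = as.character(readerId))
}

#' Two-reader consensus on the 10% step scale
#'
#' If both quantized readings agree, that value is the consensus.
#' Otherwise the consensus is the quantized mean of the two raw fractions
#' -- a deterministic stand-in for consensus-by-discussion.
#'
#' @param a,b readings from [perfusionReading()].
#' @return Consensus percentage, a multiple of 10.
#' @examples
#' consensusReading(perfusionReading(23), perfusionReading(31, "B"))
#' @export
consensusReading <- function(a, b) {
    if (a$quantized == b$quantized)
        return(a$quantized)
    quantizeStep10(mean(c(a$raw, b$raw)))
}
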