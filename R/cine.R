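#' Frame timestamps of a two-clip destruction-replenishment exam
#'
#' The default acquisition protocol: a 30-second clip at injection
#' (arterial phase) and a second 30-second clip bracketing the destructive
#' flash, each sampled at \code{frameRate}. Clip intervals are half-open
#' \code{[start, end)}.
#'
#' @param clips numeric matrix with one row per clip and columns
#'   (start, end) in seconds.
#' @param frameRate frames per second.
#' @return Strictly increasing numeric vector of frame times.
#' @examples
#' head(examTimes())
#' @export
examTimes <- function(clips = rbind(c(0, 30), c(355, 385)), frameRate = 10) {
    clips <- as.matrix(clips)
    if (ncol(clips) != 2L || any(clips[, 2] <= clips[, 1]))
        stopf("clips must be rows of (start, end) with end > start")
    t <- unlist(lapply(seq_len(nrow(clips)), function(i)
        seq(clips[i, 1], clips[i, 2] - 1 / frameRate, by = 1 / frameRate)))
    if (is.unsorted(t, strictly = TRUE))
        stopf("clips must be disjoint and in increasing order")
    t
}

#' Construct a cine loop from display frames
#'
#' Assembles a [CineLoop-class] from an 8-bit display stack and its
#' acquisition metadata, e.g. when frames come from a scanner export
#' rather than from [renderCine()].
#'
#' @param frames integer array (rows x cols x frames) of display levels.
#' @param times frame timestamps in seconds; defaults to a uniform grid at
#'   \code{frameRate}.
#' @param frameRate nominal frame rate, Hz.
#' @param flash numeric of length 0 (unknown; see [detectFlash()]) or 2
#'   (onset, end) in seconds.
#' @param law the [CompressionLaw-class] in force during acquisition.
#' @param pixelSizeMm pixel size, millimetres.
#' @return A [CineLoop-class].
#' @export
cineLoop <- function(frames, times = NULL, frameRate = 10,
        flash = numeric(), law = compressionLaw(), pixelSizeMm = 0.1) {
    if (is.null(times))
        times <- (seq_len(dim(frames)[3]) - 1L) / frameRate
    storage.mode(frames) <- "integer"
    new("CineLoop", frames = frames, times = as.numeric(times),
        frameRate = frameRate, flash = as.numeric(flash), law = law,
        pixelSizeMm = pixelSizeMm)
}

#' Construct a time-intensity curve
#'
#' @param times frame timestamps, seconds, strictly increasing.
#' @param values mean linearized ROI echo power per frame, a.u.
#' @param flash numeric of length 0 or 2 (onset, end), seconds.
#' @return A [TimeIntensityCurve-class].
#' @export
timeIntensityCurve <- function(times, values, flash = numeric()) {
    new("TimeIntensityCurve", times = as.numeric(times),
        values = as.numeric(values), flash = as.numeric(flash))
}

#' Render a synthetic cine loop
#'
#' Simulates the echo-power movie of a destruction-replenishment exam over
#' a [TumorPhantom-class] and log-compresses it to 8-bit display frames.
#' Per-pixel echo power on perfused tumour pixels is
#' \code{gain * (C(t) + B(t) * receptorMap)}; necrotic and extra-tumoural
#' pixels sit at the tissue \code{background} level. Multiplicative
#' zero-mean Gaussian noise of standard deviation \code{noiseSd} emulates
#' speckle; frames within the flash interval are rendered saturated
#' (full-scale, non-physical, excluded from quantification downstream).
#'
#' @param phantom a [TumorPhantom-class].
#' @param params a [KineticParams-class]; the flash must fall inside the
#'   exam.
#' @param law a [CompressionLaw-class] for the display mapping.
#' @param noiseSd multiplicative noise standard deviation (dimensionless).
#' @param seed integer seed; the cine is a pure function of
#'   (arguments, seed).
#' @param clips,frameRate acquisition timeline, see [examTimes()].
#' @param gain scanner gain, a.u. of echo power per a.u. of concentration.
#' @param background tissue echo power on non-perfused pixels, a.u.
#' @param pixelSizeMm pixel size recorded in the metadata.
#' @return A [CineLoop-class].
#' @examples
#' ph <- tumorPhantom(dim = c(32, 32))
#' cine <- renderCine(ph, kineticParams(), compressionLaw(), seed = 1)
#' cine
#' @seealso [roiTIC()], [computeDTE()], [writeCine()]
#' @export
renderCine <- function(phantom, params, law = compressionLaw(),
        noiseSd = 0, seed = 1L, clips = rbind(c(0, 30), c(355, 385)),
        frameRate = 10, gain = 1, background = 1, pixelSizeMm = 0.1) {
    stopifnot(is(phantom, "TumorPhantom"), is(params, "KineticParams"))
    validObject(phantom)
    times <- examTimes(clips, frameRate)
    onset <- params@flashOnset
    fEnd <- onset + params@flashDuration
    if (onset < min(times) || fEnd > max(times))
        stopf("flash interval [%g, %g] falls outside the exam", onset, fEnd)
    circ <- simulateCirculating(params, times)
    circFree <- simulateCirculating(params, times, applyFlash = FALSE)
    bound <- simulateBound(circFree, times, rho = 1, kOn = params@kOn,
        flash = c(onset, fEnd))
    nr <- nrow(phantom@tumorMask); nc <- ncol(phantom@tumorMask)
    nf <- length(times)
    perf <- phantom@tumorMask & !phantom@necroticMask
    rmap <- phantom@receptorMap
    E <- array(background, dim = c(nr, nc, nf))
    pIdx <- which(perf)
    for (i in seq_len(nf))
        E[pIdx + (i - 1L) * nr * nc] <-
            gain * (circ[i] + bound[i] * rmap[pIdx])
    if (noiseSd > 0) {
        noise <- withSeed(seed,
            pmax(0, 1 + stats::rnorm(length(E), sd = noiseSd)))
        E <- E * noise
    }
    D <- logCompress(E, law)
    inFlash <- times >= onset & times < fEnd
    if (any(inFlash))
        D[, , inFlash] <- law@levels - 1L   # saturated high-MI frames
    new("CineLoop", frames = D, times = times, frameRate = frameRate,
        flash = c(onset, fEnd), law = law, pixelSizeMm = pixelSizeMm)
}
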