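#' Detect the destructive flash interval of a cine loop
#'
#' When the acquisition metadata records the flash interval it is returned
#' directly. Otherwise the high-MI frames are recognised from the frames
#' themselves: the maximal run of frames whose mean display intensity
#' exceeds \code{median + k * MAD} of all frame means (saturated flash
#' frames stand far above the contrast signal).
#'
#' @param cine a [CineLoop-class] with at least 10 frames.
#' @param k robust threshold multiplier (default 6).
#' @return Numeric \code{c(onset, end)} in seconds; the end is the
#'   timestamp following the last flash frame.
#' @examples
#' ph <- tumorPhantom(dim = c(32, 32))
#' cine <- renderCine(ph, kineticParams(), seed = 1)
#' detectFlash(cine)
#' @export
detectFlash <- function(cine, k = 6) {
    stopifnot(is(cine, "CineLoop"))
    if (dim(cine@frames)[3] < 10L)
        stopf("at least 10 frames are required for flash detection")
    if (length(cine@flash) == 2L)
        return(cine@flash)
    m <- apply(cine@frames, 3, mean)
    thr <- stats::median(m) + k * stats::mad(m)
    hot <- m > thr
    if (!any(hot))
        stopf("no flash detected: no metadata and no high-intensity frame run")
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hotRuns <- which(r$values)
    best <- hotRuns[which.max(r$lengths[hotRuns])]
    i0 <- starts[best]; i1 <- ends[best]
    t <- cine@times
    end <- if (i1 < length(t)) t[i1 + 1L] else t[i1] + 1 / cine@frameRate
    c(t[i0], end)
}

#' Linearized ROI time-intensity curve of a cine loop
#'
#' For every frame, the mean over ROI pixels of the linearized display
#' values: relative echo power proportional to the number of microbubbles
#' per unit area in the region.
#'
#' @param cine a [CineLoop-class].
#' @param roi logical matrix selecting the region of interest (typically
#'   the whole tumour area); must be non-empty and match the frame size.
#' @param law compression law; defaults to the cine's own.
#' @return A [TimeIntensityCurve-class] carrying the cine's flash interval
#'   when one is recorded.
#' @examples
#' ph <- tumorPhantom(dim = c(32, 32))
#' cine <- renderCine(ph, kineticParams(), seed = 1)
#' tic <- roiTIC(cine, tumorMask(ph))
#' tic
#' @seealso [computeDTE()], [peakEnhancementFrame()]
#' @export
roiTIC <- function(cine, roi, law = compressionLawOf(cine)) {
    stopifnot(is(cine, "CineLoop"))
    assertMask(roi, "roi")
    d <- dim(cine@frames)
    if (!identical(dim(roi), d[1:2]))
        stopf("roi dimensions must match the frames")
    if (!any(roi))
        stopf("roi is empty")
    lut <- linearizeLUT(law)
    idx <- which(roi)
    vals <- vapply(seq_len(d[3]), function(i) {
        f <- cine@frames[, , i]
        mean(lut[f[idx] + 1L])
    }, numeric(1))
    new("TimeIntensityCurve", times = cine@times, values = vals,
        flash = cine@flash)
}

#' Differential targeted enhancement from a time-intensity curve
#'
#' Averages the linearized ROI echo power over the window of
#' \code{preDuration} seconds before flash onset (TE_bd: bound plus
#' circulating bubbles) and the window of \code{postDuration} seconds
#' opening \code{postOffset} seconds after flash onset (TE_ad: circulating
#' bubbles only, after replenishment), and subtracts:
#' dTE = TE_bd - TE_ad, proportional to the receptor-bound bubble pool.
#' Windows are half-open \code{[start, end)} in exam time; frames are
#' assigned by timestamp and flash frames never enter either window. dTE
#' may be negative on noisy input and is not clamped (downstream
#' statistics are rank-based).
#'
#' @param tic a [TimeIntensityCurve-class] with a known flash interval.
#' @param windows a [QuantWindows-class].
#' @return A [DTEResult-class].
#' @examples
#' ph <- tumorPhantom(dim = c(32, 32))
#' cine <- renderCine(ph, kineticParams(), seed = 1)
#' computeDTE(roiTIC(cine, tumorMask(ph)))
#' @export
computeDTE <- function(tic, windows = quantWindows()) {
    stopifnot(is(tic, "TimeIntensityCurve"), is(windows, "QuantWindows"))
    validObject(windows)
    if (length(tic@flash) != 2L)
        stopf("the curve has no flash interval; run detectFlash() first")
    onset <- tic@flash[1]; fEnd <- tic@flash[2]
    t <- tic@times
    inFlash <- t >= onset & t < fEnd
    pre <- t >= onset - windows@preDuration & t < onset & !inFlash
    post <- t >= onset + windows@postOffset &
        t < onset + windows@postOffset + windows@postDuration & !inFlash
    if (!any(pre))
        stopf("pre-flash window [%g, %g) contains no frames",
            onset - windows@preDuration, onset)
    if (!any(post))
        stopf("post-flash window [%g, %g) contains no frames",
            onset + windows@postOffset,
            onset + windows@postOffset + windows@postDuration)
    teBd <- mean(tic@values[pre])
    teAd <- mean(tic@values[post])
    new("DTEResult", teBd = teBd, teAd = teAd, dte = teBd - teAd,
        nFramesPre = sum(pre), nFramesPost = sum(post))
}
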