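#' @importFrom methods new validObject slot show is setClass setGeneric
#'   setMethod setValidity representation prototype slotNames
NULL

#' Accessors for mbceus objects
#'
#' Read-only accessors for the slots of the imaging containers; slot access
#' via \code{@} is discouraged outside the package.
#'
#' @param x an mbceus object.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("flashInterval", function(x) standardGeneric("flashInterval"))

#' @rdname accessors
#' @export
setGeneric("compressionLawOf", function(x) standardGeneric("compressionLawOf"))

#' @rdname accessors
#' @export
setGeneric("tumorMask", function(x) standardGeneric("tumorMask"))

#' @rdname accessors
#' @export
setGeneric("necroticMask", function(x) standardGeneric("necroticMask"))

#' @rdname accessors
#' @export
setGeneric("padMask", function(x) standardGeneric("padMask"))

#' @rdname accessors
#' @export
setGeneric("receptorMap", function(x) standardGeneric("receptorMap"))

#' @rdname accessors
#' @export
setGeneric("ticValues", function(x) standardGeneric("ticValues"))

#' @rdname accessors
#' @export
setGeneric("strainImages", function(x) standardGeneric("strainImages"))

#' @rdname accessors
#' @export
setGeneric("teBd", function(x) standardGeneric("teBd"))

#' @rdname accessors
#' @export
setGeneric("teAd", function(x) standardGeneric("teAd"))

#' @rdname accessors
#' @export
setGeneric("dte", function(x) standardGeneric("dte"))

#' @rdname accessors
#' @export
setGeneric("replicateRatios", function(x) standardGeneric("replicateRatios"))

#' @rdname accessors
#' @export
setGeneric("meanRatio", function(x) standardGeneric("meanRatio"))

#' @rdname accessors
#' @export
setGeneric("drugOnDays", function(x) standardGeneric("drugOnDays"))

#' Tumour-to-pad strain ratio
#'
#' @param x a strain image (numeric matrix) or a [StrainPair-class].
#' @param tumorRoi,padRoi logical matrices selecting the tumour and the
#'   reference-pad pixels; for a [StrainPair-class] they default to its
#'   own masks.
#' @return For a matrix, a single ratio; for a [StrainPair-class], one
#'   ratio per replicate image.
#' @export
setGeneric("strainRatio",
    function(x, tumorRoi, padRoi) standardGeneric("strainRatio"))

## ---- accessor methods ----

#' @rdname accessors
setMethod("frames", "CineLoop", function(x) x@frames)
#' @rdname accessors
setMethod("frameTimes", "CineLoop", function(x) x@times)
#' @rdname accessors
setMethod("frameTimes", "TimeIntensityCurve", function(x) x@times)
#' @rdname accessors
setMethod("flashInterval", "CineLoop", function(x) x@flash)
#' @rdname accessors
setMethod("flashInterval", "TimeIntensityCurve", function(x) x@flash)
#' @rdname accessors
setMethod("compressionLawOf", "CineLoop", function(x) x@law)
#' @rdname accessors
setMethod("tumorMask", "TumorPhantom", function(x) x@tumorMask)
#' @rdname accessors
setMethod("necroticMask", "TumorPhantom", function(x) x@necroticMask)
#' @rdname accessors
setMethod("padMask", "TumorPhantom", function(x) x@padMask)
#' @rdname accessors
setMethod("receptorMap", "TumorPhantom", function(x) x@receptorMap)
#' @rdname accessors
setMethod("tumorMask", "StrainPair", function(x) x@tumorMask)
#' @rdname accessors
setMethod("padMask", "StrainPair", function(x) x@padMask)
#' @rdname accessors
setMethod("ticValues", "TimeIntensityCurve", function(x) x@values)
#' @rdname accessors
setMethod("strainImages", "StrainPair", function(x) x@strain)
#' @rdname accessors
setMethod("teBd", "DTEResult", function(x) x@teBd)
#' @rdname accessors
setMethod("teAd", "DTEResult", function(x) x@teAd)
#' @rdname accessors
setMethod("dte", "DTEResult", function(x) x@dte)
#' @rdname accessors
setMethod("replicateRatios", "StrainResult", function(x) x@replicateRatios)
#' @rdname accessors
setMethod("meanRatio", "StrainResult", function(x) x@meanRatio)
#' @rdname accessors
setMethod("drugOnDays", "TreatmentSchedule", function(x) x@drugOnDays)

## ---- show methods ----

setMethod("show", "CompressionLaw", function(object) {
    cat(sprintf("CompressionLaw: %g dB dynamic range, full scale %g a.u., %d levels\n",
        object@drDb, object@eRef, object@levels))
})

setMethod("show", "KineticParams", function(object) {
    cat("KineticParams\n")
    cat(sprintf("  bolus: amplitude %g a.u., peak %g s, shape %g\n",
        object@bolusAmplitude, object@bolusPeakTime, object@bolusShape))
    cat(sprintf("  recirculation: fraction %g, tau %g s, washout tau %g s\n",
        object@recircFraction, object@recircTau, object@washoutTau))
    cat(sprintf("  binding: rho %g, k_on %g 1/(a.u. s)\n", object@rho, object@kOn))
    cat(sprintf("  flash: %g-%g s, replenish tau %g s\n", object@flashOnset,
        object@flashOnset + object@flashDuration, object@replenishTau))
})

setMethod("show", "TumorPhantom", function(object) {
    d <- dim(object@tumorMask)
    cat(sprintf("TumorPhantom %dx%d: %d tumour px (%d necrotic), %d pad px\n",
        d[1], d[2], sum(object@tumorMask), sum(object@necroticMask),
        sum(object@padMask)))
})

setMethod("show", "CineLoop", function(object) {
    d <- dim(object@frames)
    cat(sprintf("CineLoop: %d frames of %dx%d px at %g Hz, t = %.1f-%.1f s\n",
        d[3], d[1], d[2], object@frameRate, min(object@times), max(object@times)))
    if (length(object@flash))
        cat(sprintf("  flash: %.1f-%.1f s\n", object@flash[1], object@flash[2]))
    show(object@law)
})

setMethod("show", "TimeIntensityCurve", function(object) {
    cat(sprintf("TimeIntensityCurve: %d frames, t = %.1f-%.1f s, %.3g-%.3g a.u.\n",
        length(object@times), min(object@times), max(object@times),
        min(object@values), max(object@values)))
    if (length(object@flash))
        cat(sprintf("  flash: %.1f-%.1f s\n", object@flash[1], object@flash[2]))
})

setMethod("show", "DTEResult", function(object) {
    cat(sprintf("DTEResult: TE_bd %.4g a.u. (%d frames), TE_ad %.4g a.u. (%d frames), dTE %.4g a.u.\n",
        object@teBd, object@nFramesPre, object@teAd, object@nFramesPost,
        object@dte))
})

setMethod("show", "StrainPair", function(object) {
    d <- dim(object@tumorMask)
    cat(sprintf("StrainPair: %d replicate %dx%d strain images, %d tumour / %d pad px\n",
        length(object@strain), d[1], d[2], sum(object@tumorMask),
        sum(object@padMask)))
})

setMethod("show", "StrainResult", function(object) {
    cat(sprintf("StrainResult: mean elasticity ratio %.3f (replicates %s)\n",
        object@meanRatio,
        paste(sprintf("%.3f", object@replicateRatios), collapse = ", ")))
})

setMethod("show", "TreatmentSchedule", function(object) {
    days <- if (length(object@drugOnDays))
        paste(object@drugOnDays, collapse = ",") else "none (placebo)"
    cat(sprintf("TreatmentSchedule group %d: drug on days %s\n",
        object@groupId, days))
})

setMethod("show", "GrowthParams", function(object) {
    cat(sprintf("GrowthParams: V0 %g mm^3, rates %g (untreated) / %g (on drug) 1/day, rebound x%g\n",
        object@baselineVolume, object@growthRateUntreated,
        object@growthRateOnDrug, object@reboundMultiplier))
})
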