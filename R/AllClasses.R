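#' Logarithmic display-compression law
#'
#' Parameters of the mapping between relative echo power (arbitrary units)
#' and the 8-bit display intensity produced by the scanner. The forward map
#' compresses a \code{drDb}-decibel dynamic range ending at full scale
#' \code{eRef} onto the integer levels \code{0..levels-1}; \code{linearize()}
#' inverts it to recover quantities proportional to echo power.
#'
#' @slot drDb displayed dynamic range in decibels (> 0).
#' @slot eRef echo power (a.u.) mapped to full scale (> 0).
#' @slot levels number of display levels (256 for 8-bit displays).
#'
#' @seealso [logCompress()], [linearize()], [compressionLaw()]
#' @export
setClass("CompressionLaw",
    representation(drDb = "numeric", eRef = "numeric", levels = "integer"),
    prototype(drDb = 40, eRef = 1000, levels = 256L))

setValidity("CompressionLaw", function(object) {
    msg <- character()
    if (length(object@drDb) != 1L || !is.finite(object@drDb) || object@drDb <= 0)
        msg <- c(msg, "drDb must be a single positive number")
    if (length(object@eRef) != 1L || !is.finite(object@eRef) || object@eRef <= 0)
        msg <- c(msg, "eRef must be a single positive number")
    if (length(object@levels) != 1L || object@levels < 2L)
        msg <- c(msg, "levels must be an integer >= 2")
    if (length(msg)) msg else TRUE
})

#' Constructor for a display-compression law
#'
#' @param drDb dynamic range in dB. The scanner setting emulated by default
#'   in simulations is 40 dB; the narrow 7 dB clinical setting used in the
#'   contrast studies this package targets can be requested explicitly.
#' @param eRef echo power (a.u.) mapped to full scale.
#' @param levels number of display levels (default 256, i.e. 8-bit).
#' @return A [CompressionLaw-class] object.
#' @examples
#' law <- compressionLaw(drDb = 7, eRef = 100)
#' logCompress(100, law)   # full scale -> 255
#' @export
compressionLaw <- function(drDb = 40, eRef = 1000, levels = 256L) {
    new("CompressionLaw", drDb = as.numeric(drDb), eRef = as.numeric(eRef),
        levels = as.integer(levels))
}

#' Kinetic parameters of a simulated targeted-microbubble exam
#'
#' Describes the bolus wash-in of circulating microbubbles (gamma-variate
#' first pass plus a slowly-equilibrating recirculation plateau), the
#' receptor-binding rate of the targeted agent, and the destructive
#' high-mechanical-index flash of a destruction-replenishment exam.
#'
#' @slot bolusAmplitude peak first-pass concentration, a.u.
#' @slot bolusPeakTime time of the first-pass peak, seconds.
#' @slot bolusShape dimensionless gamma-variate shape (> 0).
#' @slot washoutTau clearance time constant of the recirculating pool,
#'   seconds; \code{Inf} models clearance negligible within the exam.
#' @slot recircFraction recirculation plateau level relative to the bolus
#'   peak (dimensionless, >= 0).
#' @slot recircTau equilibration time constant of the recirculating pool,
#'   seconds.
#' @slot rho receptor density (dimensionless, >= 0) used when a scalar
#'   density is needed; pixelwise maps live in [TumorPhantom-class].
#' @slot kOn binding rate constant, 1/(a.u. s).
#' @slot replenishTau time constant of in-plane replenishment by
#'   circulating bubbles after the flash, seconds.
#' @slot flashOnset flash onset, seconds after injection.
#' @slot flashDuration flash duration, seconds.
#'
#' @seealso [kineticParams()], [simulateCirculating()], [simulateBound()]
#' @export
setClass("KineticParams",
    representation(bolusAmplitude = "numeric", bolusPeakTime = "numeric",
        bolusShape = "numeric", washoutTau = "numeric",
        recircFraction = "numeric", recircTau = "numeric",
        rho = "numeric", kOn = "numeric", replenishTau = "numeric",
        flashOnset = "numeric", flashDuration = "numeric"))

setValidity("KineticParams", function(object) {
    msg <- character()
    one <- function(x) length(x) == 1L && !is.na(x)
    for (s in c("bolusPeakTime", "bolusShape", "washoutTau", "recircTau",
                "replenishTau", "flashDuration"))
        if (!one(slot(object, s)) || slot(object, s) <= 0)
            msg <- c(msg, paste(s, "must be a single positive number"))
    if (!one(object@bolusAmplitude) || object@bolusAmplitude < 0)
        msg <- c(msg, "bolusAmplitude must be >= 0")
    if (!one(object@recircFraction) || object@recircFraction < 0)
        msg <- c(msg, "recircFraction must be >= 0")
    if (!one(object@rho) || object@rho < 0)
        msg <- c(msg, "rho must be >= 0")
    if (!one(object@kOn) || object@kOn < 0)
        msg <- c(msg, "kOn must be >= 0")
    if (!one(object@flashOnset) || object@flashOnset <= object@bolusPeakTime)
        msg <- c(msg, "flashOnset must exceed bolusPeakTime")
    if (length(msg)) msg else TRUE
})

#' Constructor for exam kinetic parameters
#'
#' Defaults emulate the timeline of a destruction-replenishment exam with a
#' VEGFR2-targeted agent: bolus injection at t = 0, a 1-second destructive
#' flash at 6 minutes, and a late circulating plateau that is flat within
#' the 27-second quantification span (the structure the window-subtraction
#' analysis assumes; set a finite \code{washoutTau} to probe clearance bias).
#'
#' @param bolusAmplitude,bolusPeakTime,bolusShape,washoutTau,recircFraction,recircTau,rho,kOn,replenishTau,flashOnset,flashDuration
#'   see [KineticParams-class].
#' @return A [KineticParams-class] object.
#' @examples
#' kp <- kineticParams()
#' t <- seq(0, 385, by = 0.1)
#' c_t <- simulateCirculating(kp, t)
#' @export
kineticParams <- function(bolusAmplitude = 100, bolusPeakTime = 12,
        bolusShape = 2, washoutTau = Inf, recircFraction = 0.1,
        recircTau = 60, rho = 1, kOn = 0.03, replenishTau = 2,
        flashOnset = 360, flashDuration = 1) {
    new("KineticParams", bolusAmplitude = as.numeric(bolusAmplitude),
        bolusPeakTime = as.numeric(bolusPeakTime),
        bolusShape = as.numeric(bolusShape),
        washoutTau = as.numeric(washoutTau),
        recircFraction = as.numeric(recircFraction),
        recircTau = as.numeric(recircTau), rho = as.numeric(rho),
        kOn = as.numeric(kOn), replenishTau = as.numeric(replenishTau),
        flashOnset = as.numeric(flashOnset),
        flashDuration = as.numeric(flashDuration))
}

#' Digital tumour phantom
#'
#' Pixel-set description of a simulated imaging plane: the tumour region,
#' its non-perfused (necrotic) subregion, an optional reference-pad region
#' disjoint from the tumour, and a pixelwise receptor-density map that is
#' zero on necrotic and extra-tumoural pixels.
#'
#' @slot tumorMask logical matrix marking tumour pixels.
#' @slot necroticMask logical matrix, subset of \code{tumorMask}.
#' @slot padMask logical matrix, disjoint from \code{tumorMask}.
#' @slot receptorMap numeric matrix of per-pixel receptor density.
#'
#' @seealso [tumorPhantom()], [renderCine()]
#' @export
setClass("TumorPhantom",
    representation(tumorMask = "matrix", necroticMask = "matrix",
        padMask = "matrix", receptorMap = "matrix"))

setValidity("TumorPhantom", function(object) {
    msg <- character()
    d <- dim(object@tumorMask)
    for (s in c("tumorMask", "necroticMask", "padMask"))
        if (!is.logical(slot(object, s)))
            msg <- c(msg, paste(s, "must be logical"))
    if (!identical(dim(object@necroticMask), d) ||
        !identical(dim(object@padMask), d) ||
        !identical(dim(object@receptorMap), d))
        msg <- c(msg, "all masks and the receptor map must share dimensions")
    else {
        if (any(object@necroticMask & !object@tumorMask))
            msg <- c(msg, "necroticMask must be a subset of tumorMask")
        if (any(object@padMask & object@tumorMask))
            msg <- c(msg, "padMask must be disjoint from tumorMask")
        if (any(object@receptorMap < 0))
            msg <- c(msg, "receptorMap must be non-negative")
        if (any(object@receptorMap[object@necroticMask] != 0))
            msg <- c(msg, "receptorMap must be zero on necrotic pixels")
        if (any(object@receptorMap[!object@tumorMask] != 0))
            msg <- c(msg, "receptorMap must be zero outside the tumour")
    }
    if (length(msg)) msg else TRUE
})

#' Cine loop of 8-bit display frames with acquisition metadata
#'
#' An ordered stack of log-compressed 8-bit display frames, each with an
#' acquisition timestamp, together with the compression law and (when the
#' exam included one) the destructive-flash interval.
#'
#' @slot frames integer array (rows x cols x frames) of display levels.
#' @slot times numeric vector of frame timestamps, seconds after injection.
#' @slot frameRate nominal frame rate, Hz.
#' @slot flash numeric of length 0 (no flash) or 2 (onset, end) in seconds.
#' @slot law the [CompressionLaw-class] in force during acquisition.
#' @slot pixelSizeMm pixel size, millimetres.
#'
#' @seealso [renderCine()], [roiTIC()], [detectFlash()], [readCine()]
#' @export
setClass("CineLoop",
    representation(frames = "array", times = "numeric",
        frameRate = "numeric", flash = "numeric", law = "CompressionLaw",
        pixelSizeMm = "numeric"))

setValidity("CineLoop", function(object) {
    msg <- character()
    d <- dim(object@frames)
    if (length(d) != 3L)
        msg <- c(msg, "frames must be a 3-d array (rows x cols x frames)")
    else if (d[3] != length(object@times))
        msg <- c(msg, "one timestamp per frame required")
    if (is.unsorted(object@times, strictly = TRUE))
        msg <- c(msg, "frame times must be strictly increasing")
    if (any(object@frames < 0 | object@frames > object@law@levels - 1L))
        msg <- c(msg, "frames must hold display levels in range")
    if (!length(object@flash) %in% c(0L, 2L))
        msg <- c(msg, "flash must be numeric of length 0 or 2")
    if (length(object@flash) == 2L && diff(object@flash) <= 0)
        msg <- c(msg, "flash end must exceed flash onset")
    if (length(msg)) msg else TRUE
})

#' Linearized region-of-interest time-intensity curve
#'
#' Per-frame mean linearized echo power (a.u.) over a region of interest,
#' the quantity proportional to the number of microbubbles per unit area in
#' the region.
#'
#' @slot times frame timestamps, seconds.
#' @slot values mean linearized echo power per frame, a.u. (>= 0).
#' @slot flash numeric of length 0 or 2, the flash interval if known.
#'
#' @seealso [roiTIC()], [computeDTE()], [peakEnhancementFrame()]
#' @export
setClass("TimeIntensityCurve",
    representation(times = "numeric", values = "numeric", flash = "numeric"))

setValidity("TimeIntensityCurve", function(object) {
    msg <- character()
    if (length(object@times) != length(object@values))
        msg <- c(msg, "times and values must have equal length")
    if (is.unsorted(object@times, strictly = TRUE))
        msg <- c(msg, "times must be strictly increasing")
    if (any(object@values < 0))
        msg <- c(msg, "values must be non-negative")
    if (!length(object@flash) %in% c(0L, 2L))
        msg <- c(msg, "flash must be numeric of length 0 or 2")
    if (length(msg)) msg else TRUE
})

#' Quantification windows of a destruction-replenishment exam
#'
#' The averaging windows used for differential targeted enhancement: the
#' \code{preDuration} seconds immediately before the flash (bound plus
#' circulating bubbles) and the \code{postDuration} seconds starting
#' \code{postOffset} seconds after flash onset (circulating bubbles only,
#' after replenishment).
#'
#' @slot preDuration seconds before flash onset averaged into TE_bd.
#' @slot postOffset seconds after flash onset at which the late window opens.
#' @slot postDuration length of the late window, seconds.
#'
#' @seealso [computeDTE()]
#' @export
setClass("QuantWindows",
    representation(preDuration = "numeric", postOffset = "numeric",
        postDuration = "numeric"))

setValidity("QuantWindows", function(object) {
    ok <- vapply(c("preDuration", "postOffset", "postDuration"),
        function(s) { v <- slot(object, s); length(v) == 1L && is.finite(v) && v > 0 },
        logical(1))
    if (all(ok)) TRUE else "all window parameters must be single positive numbers"
})

#' Constructor for quantification windows
#'
#' @param preDuration,postOffset,postDuration window parameters in seconds;
#'   the defaults (2, 15, 10) are the convention of the quantification
#'   software this pipeline models.
#' @return A [QuantWindows-class] object.
#' @export
quantWindows <- function(preDuration = 2, postOffset = 15, postDuration = 10) {
    new("QuantWindows", preDuration = as.numeric(preDuration),
        postOffset = as.numeric(postOffset),
        postDuration = as.numeric(postDuration))
}

#' Differential targeted enhancement result
#'
#' @slot teBd mean linearized echo power before destruction, a.u.
#' @slot teAd mean linearized echo power after destruction and
#'   replenishment, a.u.
#' @slot dte \code{teBd - teAd}, a.u.; proportional to the receptor-bound
#'   bubble pool. May be negative on noisy input (never clamped).
#' @slot nFramesPre,nFramesPost frame counts entering each mean.
#'
#' @seealso [computeDTE()]
#' @export
setClass("DTEResult",
    representation(teBd = "numeric", teAd = "numeric", dte = "numeric",
        nFramesPre = "integer", nFramesPost = "integer"))

setValidity("DTEResult", function(object) {
    msg <- character()
    if (!isTRUE(all.equal(object@dte, object@teBd - object@teAd)))
        msg <- c(msg, "dte must equal teBd - teAd")
    if (object@nFramesPre < 1L || object@nFramesPost < 1L)
        msg <- c(msg, "frame counts must be positive")
    if (length(msg)) msg else TRUE
})

#' Co-registered tumour / reference-pad strain images
#'
#' Replicate strain images of the same plane (three per examination in the
#' protocol this package models), with masks for the tumour and for the
#' reference pad of constant known consistency interposed between probe and
#' tumour.
#'
#' @slot strain list of numeric matrices, one per replicate compression.
#' @slot tumorMask,padMask logical matrices; non-empty and disjoint.
#'
#' @seealso [simulateStrainPair()], [strainRatio()]
#' @export
setClass("StrainPair",
    representation(strain = "list", tumorMask = "matrix", padMask = "matrix"))

setValidity("StrainPair", function(object) {
    msg <- character()
    if (!length(object@strain) ||
        !all(vapply(object@strain, is.matrix, logical(1))))
        msg <- c(msg, "strain must be a non-empty list of matrices")
    if (!is.logical(object@tumorMask) || !is.logical(object@padMask))
        msg <- c(msg, "masks must be logical matrices")
    else {
        if (!any(object@tumorMask) || !any(object@padMask))
            msg <- c(msg, "tumour and pad masks must be non-empty")
        if (any(object@tumorMask & object@padMask))
            msg <- c(msg, "tumour and pad masks must be disjoint")
    }
    if (length(msg)) msg else TRUE
})

#' Summarized elasticity-ratio measurement
#'
#' @slot replicateRatios tumour-to-pad strain ratios of the replicate
#'   compressions (three in the modelled protocol), all > 0.
#' @slot meanRatio arithmetic mean of the replicates, the per-examination
#'   elasticity ratio ("ELX2/1"); higher means softer tumour.
#'
#' @seealso [triplicateMean()]
#' @export
setClass("StrainResult",
    representation(replicateRatios = "numeric", meanRatio = "numeric"))

setValidity("StrainResult", function(object) {
    msg <- character()
    if (any(object@replicateRatios <= 0))
        msg <- c(msg, "ratios must be positive")
    if (!isTRUE(all.equal(object@meanRatio, mean(object@replicateRatios))))
        msg <- c(msg, "meanRatio must be the mean of replicateRatios")
    if (length(msg)) msg else TRUE
})

#' Treatment schedule of a study group
#'
#' @slot groupId integer group label.
#' @slot drugOnDays integer vector of study days (within 0..13) on which
#'   the antiangiogenic drug is administered; empty for placebo.
#'
#' @seealso [treatmentSchedule()], [defaultSchedules()]
#' @export
setClass("TreatmentSchedule",
    representation(groupId = "integer", drugOnDays = "integer"))

setValidity("TreatmentSchedule", function(object) {
    msg <- character()
    if (length(object@groupId) != 1L)
        msg <- c(msg, "groupId must be a single integer")
    if (length(object@drugOnDays) &&
        (any(object@drugOnDays < 0L) || any(object@drugOnDays > 13L) ||
         anyDuplicated(object@drugOnDays)))
        msg <- c(msg, "drugOnDays must be distinct days within 0..13")
    if (length(msg)) msg else TRUE
})

#' Constructor for a treatment schedule
#'
#' @param groupId integer group label.
#' @param drugOnDays days on drug (integer vector, possibly empty).
#' @return A [TreatmentSchedule-class] object.
#' @export
treatmentSchedule <- function(groupId, drugOnDays = integer()) {
    new("TreatmentSchedule", groupId = as.integer(groupId),
        drugOnDays = sort(as.integer(drugOnDays)))
}

#' The three treatment schedules of the interruption study design
#'
#' Group 1: placebo throughout. Group 2: drug on days 0-4, interrupted on
#' days 5-8, resumed on days 9-13. Group 3: drug on days 0-4, then
#' permanently stopped.
#'
#' @return A list of three [TreatmentSchedule-class] objects.
#' @examples
#' defaultSchedules()
#' @export
defaultSchedules <- function() {
    list(treatmentSchedule(1L, integer()),
         treatmentSchedule(2L, c(0:4, 9:13)),
         treatmentSchedule(3L, 0:4))
}

#' Growth-model parameters of a simulated xenograft cohort
#'
#' Per-day piecewise-exponential volume growth: the untreated rate applies
#' off drug, the on-drug rate while dosed, and after a permanent stop the
#' untreated rate is multiplied by \code{reboundMultiplier} (rebound
#' neoangiogenesis). A temporary interruption uses the plain untreated rate.
#'
#' @slot baselineVolume median day-0 volume, mm^3.
#' @slot growthRateUntreated,growthRateOnDrug exponential rates, 1/day.
#' @slot reboundMultiplier multiplier (>= 1) on the untreated rate after
#'   permanent drug withdrawal.
#' @slot animalNoiseSd lognormal sd of per-animal baseline volume.
#' @slot rateNoiseSd lognormal sd of per-animal growth-rate multiplier.
#'
#' @seealso [growthParams()], [simulateGrowthCohort()]
#' @export
setClass("GrowthParams",
    representation(baselineVolume = "numeric",
        growthRateUntreated = "numeric", growthRateOnDrug = "numeric",
        reboundMultiplier = "numeric", animalNoiseSd = "numeric",
        rateNoiseSd = "numeric"))

setValidity("GrowthParams", function(object) {
    msg <- character()
    if (object@baselineVolume <= 0)
        msg <- c(msg, "baselineVolume must be positive")
    if (object@growthRateOnDrug >= object@growthRateUntreated)
        msg <- c(msg, "growthRateOnDrug must be below growthRateUntreated")
    if (object@reboundMultiplier < 1)
        msg <- c(msg, "reboundMultiplier must be >= 1")
    if (object@animalNoiseSd < 0 || object@rateNoiseSd < 0)
        msg <- c(msg, "noise sds must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Constructor for growth-model parameters
#'
#' Defaults emulate a sorafenib-interruption xenograft study: untreated
#' doubling in about nine days, near growth arrest on drug, and a modest
#' rebound after permanent withdrawal that brings regrowth back to the
#' untreated pace.
#'
#' @param baselineVolume,growthRateUntreated,growthRateOnDrug,reboundMultiplier,animalNoiseSd,rateNoiseSd
#'   see [GrowthParams-class].
#' @return A [GrowthParams-class] object.
#' @export
growthParams <- function(baselineVolume = 143, growthRateUntreated = 0.075,
        growthRateOnDrug = 0.01, reboundMultiplier = 1.05,
        animalNoiseSd = 0.45, rateNoiseSd = 0.15) {
    new("GrowthParams", baselineVolume = as.numeric(baselineVolume),
        growthRateUntreated = as.numeric(growthRateUntreated),
        growthRateOnDrug = as.numeric(growthRateOnDrug),
        reboundMultiplier = as.numeric(reboundMultiplier),
        animalNoiseSd = as.numeric(animalNoiseSd),
        rateNoiseSd = as.numeric(rateNoiseSd))
}
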