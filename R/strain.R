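#' Simulate replicate tumour/pad strain images
#'
#' Emulates the elastography acquisition: the reference pad (known constant
#' consistency) shows uniform strain \code{padStrain}; tumour pixels show
#' \code{padStrain * trueRatio} plus zero-mean Gaussian noise of standard
#' deviation \code{noiseSd} (absolute, in strain units). The replicate
#' images of one call differ only by noise, like repeat manual
#' compressions.
#'
#' @param trueRatio true tumour-to-pad strain ratio, > 0.
#' @param noiseSd standard deviation of the tumour strain noise.
#' @param phantom a [TumorPhantom-class] whose \code{tumorMask} and
#'   \code{padMask} are both non-empty.
#' @param seed integer seed.
#' @param padStrain pad strain level (arbitrary strain units).
#' @param nReplicates number of replicate images (3 in the modelled
#'   protocol).
#' @return A [StrainPair-class].
#' @examples
#' ph <- tumorPhantom(dim = c(48, 48), padRows = 8)
#' sp <- simulateStrainPair(1.33, noiseSd = 0, phantom = ph, seed = 1)
#' strainRatio(sp)
#' @export
simulateStrainPair <- function(trueRatio, noiseSd = 0, phantom,
        seed = 1L, padStrain = 1, nReplicates = 3L) {
    if (length(trueRatio) != 1L || is.na(trueRatio) || trueRatio <= 0)
        stopf("trueRatio must be a single positive number")
    if (noiseSd < 0) stopf("noiseSd must be non-negative")
    stopifnot(is(phantom, "TumorPhantom"))
    if (!any(phantom@padMask))
        stopf("phantom must have a non-empty pad region (padRows > 0)")
    tm <- phantom@tumorMask; pm <- phantom@padMask
    nT <- sum(tm)
    withSeed(seed, {
        imgs <- lapply(seq_len(nReplicates), function(r) {
            img <- matrix(0, nrow(tm), ncol(tm))
            img[pm] <- padStrain
            img[tm] <- padStrain * trueRatio +
                if (noiseSd > 0) stats::rnorm(nT, sd = noiseSd) else 0
            img
        })
        new("StrainPair", strain = imgs, tumorMask = tm, padMask = pm)
    })
}

#' @describeIn strainRatio ratio of mean tumour strain to mean pad strain
#'   for a single strain image.
#' @export
setMethod("strainRatio", "matrix", function(x, tumorRoi, padRoi) {
    assertMask(tumorRoi, "tumorRoi"); assertMask(padRoi, "padRoi")
    if (!any(tumorRoi) || !any(padRoi))
        stopf("both ROIs must be non-empty")
    if (any(tumorRoi & padRoi))
        stopf("tumour and pad ROIs must be disjoint")
    padMean <- mean(x[padRoi])
    if (padMean <= 0)
        stopf("pad mean strain is not positive; cannot form a ratio")
    mean(x[tumorRoi]) / padMean
})

#' @describeIn strainRatio one ratio per replicate image of a
#'   [StrainPair-class]; ROIs default to the pair's own masks.
#' @export
setMethod("strainRatio", "StrainPair", function(x, tumorRoi, padRoi) {
    if (missing(tumorRoi)) tumorRoi <- x@tumorMask
    if (missing(padRoi)) padRoi <- x@padMask
    vapply(x@strain, strainRatio, numeric(1), tumorRoi = tumorRoi,
        padRoi = padRoi)
})

#' Mean of triplicate elasticity-ratio measurements
#'
#' The protocol takes three strain measurements per tumour under one
#' anaesthesia and uses their arithmetic mean; the replicates are retained
#' for audit.
#'
#' @param ratios numeric vector of exactly three positive ratios.
#' @return A [StrainResult-class].
#' @examples
#' triplicateMean(c(1.2, 1.3, 1.4))
#' @export
triplicateMean <- function(ratios) {
    if (length(ratios) != 3L)
        stopf("exactly three replicate ratios are required, got %d",
            length(ratios))
    if (any(!is.finite(ratios)) || any(ratios <= 0))
        stopf("replicate ratios must all be positive")
    new("StrainResult", replicateRatios = as.numeric(ratios),
        meanRatio = mean(ratios))
}
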