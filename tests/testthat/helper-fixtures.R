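# shared fixtures: everything is generated in code, nothing on disk

defaultLaw <- function() compressionLaw(drDb = 40, eRef = 1000)

smallPhantom <- function(necroticFraction = 0, rho = 1, dim = c(32L, 32L),
        padRows = 0L)
    tumorPhantom(dim = dim, necroticFraction = necroticFraction, rho = rho,
        padRows = padRows)

# cine with a given constant display level and an optional saturated run
flatCine <- function(level, nFrames = 100L, dim = c(8L, 8L),
        satFrames = integer(), law = defaultLaw(), frameRate = 10) {
    D <- array(as.integer(level), dim = c(dim, nFrames))
    if (length(satFrames))
        D[, , satFrames] <- law@levels - 1L
    cineLoop(D, frameRate = frameRate, law = law)
}

# linearized peak-enhancement frame of a cine
peakFrame <- function(cine, roi) {
    tic <- roiTIC(cine, roi)
    linearize(frames(cine)[, , peakEnhancementFrame(tic)],
        compressionLawOf(cine))
}

# independent midrank computation by counting (oracle for rank-based tests)
bruteMidranks <- function(x)
    vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))

# Pearson correlation from explicit sums (oracle, avoids stats::cor)
brutePearson <- function(a, b) {
    n <- length(a)
    num <- sum(a * b) - n * mean(a) * mean(b)
    den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
    num / den
}

# the published per-animal non-enhanced percentages (both exams)
table1 <- function() list(
    exam1 = list(g1 = c(20, 0, 30, 10), g2 = c(0, 30, 0, 30, 20, 0),
        g3 = c(30, 10, 30, 0)),
    exam2 = list(g1 = c(20, 20, 50, 40), g2 = c(0, 30, 10, 20, 40, 0),
        g3 = c(10, 0, 10, 0)))
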