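test_that("phantom construction enforces the mask laws", {
    ph <- smallPhantom(necroticFraction = 0.3)
    expect_true(all(tumorMask(ph)[necroticMask(ph)]))
    expect_false(any(receptorMap(ph)[necroticMask(ph)] != 0))
    expect_false(any(receptorMap(ph)[!tumorMask(ph)] != 0))
    # exact necrotic pixel count by construction
    expect_identical(sum(necroticMask(ph)),
        as.integer(round(0.3 * sum(tumorMask(ph)))))
    pad <- tumorPhantom(dim = c(48, 48), padRows = 8)
    expect_false(any(padMask(pad) & tumorMask(pad)))
    expect_error(tumorPhantom(dim = c(32, 32), necroticFraction = 1.5),
        "necroticFraction")
})

test_that("rendered cines are deterministic in the seed", {
    ph <- smallPhantom()
    kp <- kineticParams()
    c1 <- renderCine(ph, kp, defaultLaw(), noiseSd = 0.1, seed = 5)
    c2 <- renderCine(ph, kp, defaultLaw(), noiseSd = 0.1, seed = 5)
    expect_identical(frames(c1), frames(c2))
    c3 <- renderCine(ph, kp, defaultLaw(), noiseSd = 0.1, seed = 6)
    expect_false(identical(frames(c1), frames(c3)))
})

test_that("a flash outside the exam is rejected", {
    ph <- smallPhantom()
    expect_error(renderCine(ph, kineticParams(flashOnset = 500),
        defaultLaw(), seed = 1), "outside the exam")
})

test_that("flash frames are rendered saturated", {
    ph <- smallPhantom()
    cine <- renderCine(ph, kineticParams(), defaultLaw(), seed = 1)
    t <- frameTimes(cine)
    inFlash <- t >= 360 & t < 361
    expect_true(all(frames(cine)[, , inFlash] == 255L))
})

test_that("without binding the ROI power tracks the circulating curve", {
    # conservation: noise-free, rho = 0, perfused-region ROI
    ph <- smallPhantom(rho = 0)
    kp <- kineticParams()
    law <- defaultLaw()
    cine <- renderCine(ph, kp, law, noiseSd = 0, seed = 1, gain = 1)
    tic <- roiTIC(cine, tumorMask(ph) & !necroticMask(ph))
    t <- frameTimes(cine)
    expected <- simulateCirculating(kp, t)
    inRange <- expected > 2 * linearize(0L, law) & !(t >= 360 & t < 361)
    relErr <- abs(ticValues(tic)[inRange] / expected[inRange] - 1)
    expect_lt(max(relErr), roundTripTolerance(law) + 1e-12)
})

test_that("at peak enhancement the necrotic fraction sits at background", {
    ph <- smallPhantom(necroticFraction = 0.3)
    cine <- renderCine(ph, kineticParams(), defaultLaw(), seed = 1,
        background = 1)
    E <- peakFrame(cine, tumorMask(ph))
    atBg <- E[tumorMask(ph)] < 2   # background = 1 a.u.
    expect_equal(100 * mean(atBg),
        100 * sum(necroticMask(ph)) / sum(tumorMask(ph)))
})

test_that("cine TIFF + JSON round trip preserves frames and metadata", {
    ph <- smallPhantom()
    cine <- renderCine(ph, kineticParams(), defaultLaw(), noiseSd = 0.1,
        seed = 2)
    tif <- tempfile(fileext = ".tif")
    writeCine(cine, tif)
    back <- readCine(tif)
    expect_identical(frames(back), frames(cine))
    expect_equal(frameTimes(back), frameTimes(cine))
    expect_equal(flashInterval(back), flashInterval(cine))
    expect_equal(compressionLawOf(back)@drDb, 40)
    m <- tempfile(fileext = ".tif")
    writeMask(tumorMask(ph), m)
    expect_identical(readMask(m), tumorMask(ph))
})
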