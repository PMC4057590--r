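test_that("flash detection passes metadata through and finds saturated runs", {
    ph <- smallPhantom()
    cine <- renderCine(ph, kineticParams(), defaultLaw(), seed = 1)
    expect_equal(detectFlash(cine), c(360, 361))
    # no metadata: the maximal saturated run at 10 Hz covers frames 50-59
    noMeta <- flatCine(50, nFrames = 100, satFrames = 50:59)
    expect_equal(detectFlash(noMeta), c(4.9, 5.9))
    expect_error(detectFlash(flatCine(50, nFrames = 100)),
        "no flash detected")
    expect_error(detectFlash(flatCine(50, nFrames = 5)), "10 frames")
})

test_that("ROI curves average linearized power over the region", {
    law <- compressionLaw(drDb = 7, eRef = 100)
    allBright <- flatCine(255, nFrames = 12, law = law)
    roi <- matrix(TRUE, 8, 8); roi[1, 1] <- FALSE
    tic <- roiTIC(allBright, roi)
    expect_equal(ticValues(tic), rep(100, 12))
    # half the ROI at full scale, half one decade down (10 dB law so the
    # lower region is exactly at the bottom of the range)
    law10 <- compressionLaw(drDb = 10, eRef = 100)
    D <- array(0L, dim = c(8, 8, 4))
    D[1:4, , ] <- 255L
    half <- cineLoop(D, law = law10)
    expect_equal(ticValues(roiTIC(half, matrix(TRUE, 8, 8))),
        rep(0.55 * 100, 4))
    expect_error(roiTIC(allBright, matrix(FALSE, 8, 8)), "empty")
    expect_error(roiTIC(allBright, matrix(TRUE, 4, 4)), "dimensions")
})

test_that("dTE is the difference of the two window means", {
    # constant 300 a.u. before the flash, 120 a.u. in the late window
    t <- seq(355, 385 - 0.1, by = 0.1)
    vals <- ifelse(t < 360, 300, 120)
    tic <- timeIntensityCurve(t, vals, flash = c(360, 361))
    r <- computeDTE(tic)
    expect_equal(teBd(r), 300)
    expect_equal(teAd(r), 120)
    expect_equal(dte(r), 180)
    expect_identical(dte(r), teBd(r) - teAd(r))
    expect_identical(r@nFramesPre, 20L)
    expect_identical(r@nFramesPost, 100L)
})

test_that("windows outside the exam are reported by name", {
    t <- seq(359, 365, by = 0.1)
    tic <- timeIntensityCurve(t, rep(10, length(t)), flash = c(360, 361))
    expect_error(computeDTE(tic), "post-flash window")
    t2 <- seq(360, 385, by = 0.1)
    tic2 <- timeIntensityCurve(t2, rep(10, length(t2)),
        flash = c(360, 361))
    expect_error(computeDTE(tic2), "pre-flash window")
    noFlash <- timeIntensityCurve(1:20, rep(1, 20))
    expect_error(computeDTE(noFlash), "no flash")
})

test_that("window frame assignment is half-open from flash onset", {
    # frames exactly at onset-2 and onset+15 are included, at onset excluded
    t <- c(357.9, 358, 359.9, 360, 360.5, 374.9, 375, 384.9, 385)
    vals <- rep(100, length(t))
    tic <- timeIntensityCurve(t, vals, flash = c(360, 361))
    r <- computeDTE(tic)
    expect_identical(r@nFramesPre, 2L)    # 358, 359.9
    expect_identical(r@nFramesPost, 2L)   # 375, 384.9
})

test_that("zero binding yields zero dTE within round-trip tolerance", {
    ph <- smallPhantom(rho = 0)
    law <- defaultLaw()
    cine <- renderCine(ph, kineticParams(), law, noiseSd = 0, seed = 1)
    r <- computeDTE(roiTIC(cine, tumorMask(ph)))
    expect_lt(abs(dte(r)), roundTripTolerance(law) * teBd(r) + 1e-9)
})

test_that("dTE scales with receptor density like the simulator's bound pool", {
    law <- defaultLaw()
    kp <- kineticParams()
    dtes <- vapply(c(0.5, 1, 2), function(rho) {
        ph <- smallPhantom(rho = rho)
        dte(computeDTE(roiTIC(renderCine(ph, kp, law, seed = 1),
            tumorMask(ph))))
    }, numeric(1))
    expect_equal(dtes / dtes[2], c(0.5, 1, 2), tolerance = 0.02)
})
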