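test_that("the peak frame is the arterial-phase maximum, earliest on ties", {
    t <- seq(0, 29.9, by = 0.1)
    rising <- timeIntensityCurve(t, c(seq_len(150), 150:1))
    expect_identical(peakEnhancementFrame(rising), 150L)
    flat <- timeIntensityCurve(t, rep(5, 300))
    expect_identical(peakEnhancementFrame(flat), 1L)
    expect_error(peakEnhancementFrame(flat, c(40, 50)), "no frames")
    # on a simulated bolus without binding the peak lands near the bolus
    # peak time; the 8-bit display quantizes the curve into a plateau
    # around the maximum, so the match is to within the plateau width
    ph <- smallPhantom(rho = 0)
    kp <- kineticParams()
    cine <- renderCine(ph, kp, defaultLaw(), seed = 1)
    tic <- roiTIC(cine, tumorMask(ph))
    i <- peakEnhancementFrame(tic)
    tPeak <- frameTimes(tic)[i]
    expect_lt(abs(tPeak - kp@bolusPeakTime), 2)
    expect_equal(ticValues(tic)[i],
        max(ticValues(tic)[frameTimes(tic) < 30]))
})

test_that("non-enhanced fraction equals the constructed necrotic fraction", {
    kp <- kineticParams()
    for (frac in c(0, 0.3, 0.5)) {
        ph <- smallPhantom(necroticFraction = frac)
        cine <- renderCine(ph, kp, defaultLaw(), seed = 1)
        E <- peakFrame(cine, tumorMask(ph))
        expect_equal(nonEnhancedFraction(E, tumorMask(ph)),
            100 * sum(necroticMask(ph)) / sum(tumorMask(ph)))
    }
})

test_that("degenerate inputs to the fraction are rejected", {
    E <- matrix(5, 8, 8)
    roi <- matrix(FALSE, 8, 8); roi[3:6, 3:6] <- TRUE
    expect_error(nonEnhancedFraction(E, matrix(FALSE, 8, 8)), "empty")
    expect_error(nonEnhancedFraction(E, matrix(TRUE, 8, 8)),
        "background")
    zeroBg <- E; zeroBg[!roi] <- 0
    expect_error(nonEnhancedFraction(zeroBg, roi), "degenerate")
})

test_that("enlarging the necrotic region never lowers the raw fraction", {
    kp <- kineticParams()
    fr <- vapply(c(0, 0.1, 0.2, 0.4, 0.6), function(f) {
        ph <- smallPhantom(necroticFraction = f)
        cine <- renderCine(ph, kp, defaultLaw(), seed = 1)
        nonEnhancedFraction(peakFrame(cine, tumorMask(ph)), tumorMask(ph))
    }, numeric(1))
    expect_true(all(diff(fr) >= 0))
})

test_that("the 10% step scale rounds to the nearest step, halves up", {
    expect_equal(quantizeStep10(23), 20)
    expect_equal(quantizeStep10(25), 30)
    expect_equal(quantizeStep10(0), 0)
    expect_equal(quantizeStep10(100), 100)
    expect_error(quantizeStep10(101), "\\[0, 100\\]")
    expect_error(quantizeStep10(-2), "\\[0, 100\\]")
    raws <- seq(0, 100, by = 0.5)
    q <- quantizeStep10(raws)
    expect_true(all(q %in% seq(0, 100, by = 10)))
    expect_true(all(abs(q - raws) <= 5))
})

test_that("consensus returns agreement or the quantized mean of raw reads", {
    expect_equal(consensusReading(perfusionReading(30, "A"),
        perfusionReading(30, "B")), 30)
    expect_equal(consensusReading(perfusionReading(23, "A"),
        perfusionReading(31, "B")), 30)   # mean 27 -> 30
    expect_equal(consensusReading(perfusionReading(20, "A"),
        perfusionReading(30, "B")), 30)   # mean 25, half rounds up
})

test_that("the full scoring chain reproduces published-style percentages", {
    # noise-free phantoms built from 10%-scale fractions read back exactly
    kp <- kineticParams()
    for (p in c(0, 10, 20, 30, 40, 50)) {
        ph <- smallPhantom(necroticFraction = p / 100)
        cine <- renderCine(ph, kp, defaultLaw(), seed = 1)
        E <- peakFrame(cine, tumorMask(ph))
        a <- perfusionReading(nonEnhancedFraction(E, tumorMask(ph), 2.0), "A")
        b <- perfusionReading(nonEnhancedFraction(E, tumorMask(ph), 2.5), "B")
        expect_equal(consensusReading(a, b), p)
    }
})
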