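test_that("circulating curve is zero for a zero bolus and peaks at the bolus peak time", {
    t <- seq(0, 385, by = 0.1)
    expect_equal(simulateCirculating(kineticParams(bolusAmplitude = 0), t),
        rep(0, length(t)))
    kp <- kineticParams()
    ct <- simulateCirculating(kp, t)
    expect_true(all(ct >= 0))
    expect_lt(abs(t[which.max(ct)] - kp@bolusPeakTime), 0.5)
})

test_that("post-flash circulating signal relaxes to the unflashed trajectory", {
    # 14 s after flash end with tau = 3 s is ~4.7 time constants
    kp <- kineticParams(replenishTau = 3)
    t <- seq(0, 385, by = 0.1)
    flashed <- simulateCirculating(kp, t)
    free <- simulateCirculating(kp, t, applyFlash = FALSE)
    i <- which.min(abs(t - 375))
    expect_lt(abs(flashed[i] / free[i] - 1), 0.01)
    # during the flash the in-plane signal is zero
    expect_equal(flashed[t >= 360 & t < 361], rep(0, 10))
})

test_that("kinetic parameter validation rejects non-positive time constants", {
    expect_error(kineticParams(replenishTau = 0), "positive")
    expect_error(kineticParams(bolusPeakTime = -1), "positive")
    expect_error(kineticParams(flashOnset = 5, bolusPeakTime = 12),
        "flashOnset")
})

test_that("bound pool is linear in receptor density and zeroed by the flash", {
    kp <- kineticParams()
    t <- seq(0, 385, by = 0.1)
    circ <- simulateCirculating(kp, t, applyFlash = FALSE)
    b0 <- simulateBound(circ, t, rho = 0, kOn = 0.03)
    expect_equal(b0, rep(0, length(t)))
    b1 <- simulateBound(circ, t, rho = 1, kOn = 0.03)
    b2 <- simulateBound(circ, t, rho = 2, kOn = 0.03)
    expect_equal(b2, 2 * b1)
    bf <- simulateBound(circ, t, rho = 1, kOn = 0.03, flash = c(360, 361))
    expect_true(all(bf[t >= 360] == 0))
    expect_equal(bf[t < 360], b1[t < 360])
    expect_error(simulateBound(circ, t, rho = -1, kOn = 0.03),
        "non-negative")
})

test_that("cumulative binding matches numeric quadrature of the kernel", {
    kp <- kineticParams()
    A <- kp@bolusAmplitude; tp <- kp@bolusPeakTime; a <- kp@bolusShape
    fr <- kp@recircFraction; tr <- kp@recircTau
    kernel <- function(s)
        A * (s / tp)^a * exp(a * (1 - s / tp)) +
        A * fr * (1 - exp(-s / tr))     # washoutTau = Inf by default
    t <- seq(0, 385, by = 0.05)
    circ <- simulateCirculating(kp, t, applyFlash = FALSE)
    b <- simulateBound(circ, t, rho = 1, kOn = 0.03)
    i359 <- which.min(abs(t - 359)); i180 <- which.min(abs(t - 180))
    int359 <- stats::integrate(kernel, 0, 359, rel.tol = 1e-10)$value
    int180 <- stats::integrate(kernel, 0, 180, rel.tol = 1e-10)$value
    expect_equal(b[i359] / b[i180], int359 / int180, tolerance = 1e-5)
})

test_that("pre-flash bound level is non-decreasing in rho and k_on", {
    kp <- kineticParams()
    t <- seq(0, 359, by = 0.5)
    circ <- simulateCirculating(kp, t, applyFlash = FALSE)
    atEnd <- function(rho, kOn)
        tail(simulateBound(circ, t, rho = rho, kOn = kOn), 1)
    levelsRho <- vapply(seq(0, 3, by = 0.5), atEnd, numeric(1), kOn = 0.03)
    expect_true(all(diff(levelsRho) >= 0))
    levelsKon <- vapply(seq(0.01, 0.1, by = 0.01), atEnd, numeric(1),
        rho = 1)
    expect_true(all(diff(levelsKon) >= 0))
})
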