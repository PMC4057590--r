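# a small, fast study configuration used across these tests
testConfig <- function(nPerGroup = c(2L, 2L, 2L))
    studyConfig(nPerGroup = nPerGroup, imageDim = c(24L, 24L),
        frameRate = 5)

test_that("median-of-deltas differs from delta-of-medians and the former is used", {
    starts <- c(100, 300); finals <- c(200, 450)
    perAnimal <- percentDelta(starts, finals)           # 100, 50
    medOfDeltas <- stats::median(perAnimal)             # 75
    deltaOfMedians <- percentDelta(stats::median(starts),
        stats::median(finals))                          # 62.5
    expect_false(isTRUE(all.equal(medOfDeltas, deltaOfMedians)))

    # pipeline check: group summary of volume deltas equals the median of
    # per-animal deltas, not the delta of group median volumes
    dir <- tempfile()
    cfg <- testConfig()
    simulateStudy(cfg, seed = 21, outDir = dir)
    res <- runStudy(dir, cfg)
    pa <- res$perAnimal
    g1 <- pa$animal[pa$group == 1 & pa$endpoint == "volume" &
        pa$timepoint == "day0"]
    dl <- vapply(g1, function(a) percentDelta(
        pa$value[pa$animal == a & pa$endpoint == "volume" &
            pa$timepoint == "day0"],
        pa$value[pa$animal == a & pa$endpoint == "volume" &
            pa$timepoint == "day13"]), numeric(1))
    rep13 <- res$report[res$report$endpoint == "volume_delta" &
        res$report$timepoint == "day13_vs_day0" & res$report$group == 1, ]
    expect_equal(rep13$median, stats::median(dl), tolerance = 1e-9)
})

test_that("simulate + run with one seed is byte-identical across runs", {
    cfg <- testConfig()
    outs <- lapply(1:2, function(i) {
        d <- tempfile()
        simulateStudy(cfg, seed = 33, outDir = d)
        runStudy(d, cfg, outDir = file.path(d, "out"))
        list(report = readBin(file.path(d, "out", "report.csv"), "raw",
                 5e6),
             json = readBin(file.path(d, "out", "summary.json"), "raw",
                 5e6))
    })
    expect_identical(outs[[1]]$report, outs[[2]]$report)
    expect_identical(outs[[1]]$json, outs[[2]]$json)
})

test_that("missing cohort records raise a named-gap error", {
    dir <- tempfile()
    cfg <- testConfig()
    simulateStudy(cfg, seed = 5, outDir = dir)
    tab <- readCohort(file.path(dir, "cohort.csv"))
    tab <- tab[!(tab$animal_id == "g1_a01" & tab$day == 9), ]
    writeCohort(tab, file.path(dir, "cohort.csv"))
    expect_error(runStudy(dir, cfg), "g1_a01: day 9")
})

test_that("single-animal groups give summaries but no tests, with a warning", {
    dir <- tempfile()
    cfg <- testConfig(nPerGroup = c(1L, 1L, 1L))
    simulateStudy(cfg, seed = 8, outDir = dir)
    expect_warning(res <- runStudy(dir, cfg), "tests skipped")
    expect_null(res$tests)
    expect_true(all(res$report$n == 1))
})

test_that("the pipeline reproduces the interruption study's directions of effect", {
    dir <- tempfile()
    cfg <- studyConfig(imageDim = c(24L, 24L), frameRate = 5)
    simulateStudy(cfg, seed = 104, outDir = dir)
    res <- runStudy(dir, cfg, outDir = file.path(dir, "out"))
    rep <- res$report
    med <- function(ep, tp) {
        r <- rep[rep$endpoint == ep & rep$timepoint == tp, ]
        r$median[order(r$group)]
    }
    # dTE at the second exam: permanently-stopped arm highest
    dte2 <- med("dte", "day13")
    expect_gt(dte2[3], dte2[1])
    expect_gt(dte2[3], dte2[2])
    # non-enhanced area at the second exam: placebo highest, stopped lowest
    perf2 <- med("perfusion_nonenhanced", "day13")
    expect_gt(perf2[1], perf2[3])
    # elasticity delta positive only in the re-treated arm
    eld <- med("elasticity_delta", "day11_vs_day9")
    expect_gt(eld[2], 0)
    expect_lt(eld[1], eld[2])
    expect_lt(eld[3], eld[2])
    expect_true(file.exists(file.path(dir, "out", "report.csv")))
    expect_true(file.exists(file.path(dir, "out", "summary.json")))
})
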