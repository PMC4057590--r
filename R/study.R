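#' Configuration of a simulated interruption study
#'
#' Bundles every tunable of the end-to-end pipeline: cohort sizes and
#' schedules, growth model, exam kinetics and display law, imaging
#' geometry and noise, per-group receptor densities and necrotic fractions
#' at the two contrast exams, per-group true elasticity ratios at the two
#' elastography days, and the two reader thresholds of the perfusion
#' scoring. Defaults emulate a three-arm sorafenib-interruption xenograft
#' study: 4/6/4 animals; receptor density at the second exam highest in
#' the permanently-stopped arm (rebound neoangiogenesis) and lowest under
#' resumed treatment; necrotic fractions with group medians matching the
#' published per-animal scoring; elasticity rising between the two
#' elastography days only in the re-treated arm.
#'
#' @param nPerGroup animals per group.
#' @param days volume measurement days.
#' @param examDays the two targeted-contrast exam days.
#' @param elastoDays the two elastography days.
#' @param growth a [GrowthParams-class].
#' @param schedules list of [TreatmentSchedule-class].
#' @param kinetics a [KineticParams-class] (exam timing and bolus).
#' @param law a [CompressionLaw-class].
#' @param imageDim cine frame size in pixels.
#' @param frameRate cine frame rate, Hz.
#' @param cineNoiseSd multiplicative speckle noise sd.
#' @param gain,background cine rendering levels, a.u.
#' @param rhoByGroupExam groups x exams matrix of median receptor density.
#' @param rhoCv lognormal sd of per-animal receptor density.
#' @param necroticByGroupExam groups x exams matrix of median necrotic
#'   fraction.
#' @param necroticSd per-animal Gaussian jitter of necrotic fraction
#'   (clamped to \code{[0, 0.6]}).
#' @param strainRatioByGroupDay groups x days matrix of true elasticity
#'   ratio.
#' @param strainRatioCv lognormal sd of per-animal true ratio.
#' @param strainNoiseSd strain image noise sd.
#' @param padRows pad strip height for strain phantoms, pixels.
#' @param readerThresholds the two readers' \code{thresholdFactor}s for
#'   [nonEnhancedFraction()].
#' @return A list of class \code{mbceusStudyConfig}.
#' @seealso [simulateStudy()], [runStudy()]
#' @export
studyConfig <- function(nPerGroup = c(4L, 6L, 4L),
        days = c(0, 5, 9, 11, 13), examDays = c(5, 13),
        elastoDays = c(9, 11), growth = growthParams(),
        schedules = defaultSchedules(), kinetics = kineticParams(),
        law = compressionLaw(), imageDim = c(32L, 32L), frameRate = 10,
        cineNoiseSd = 0.1, gain = 1, background = 1,
        rhoByGroupExam = rbind(c(0.95, 0.90), c(0.62, 0.60),
            c(0.45, 1.65)),
        rhoCv = 0.3,
        necroticByGroupExam = rbind(c(0.15, 0.30), c(0.10, 0.15),
            c(0.20, 0.05)),
        necroticSd = 0.06,
        strainRatioByGroupDay = rbind(c(1.34, 1.15), c(1.10, 1.33),
            c(1.14, 1.08)),
        strainRatioCv = 0.06, strainNoiseSd = 0.05, padRows = 8L,
        readerThresholds = c(2.0, 2.5)) {
    ng <- length(schedules)
    stopifnot(length(nPerGroup) == ng,
        nrow(rhoByGroupExam) == ng, ncol(rhoByGroupExam) == 2L,
        nrow(necroticByGroupExam) == ng,
        nrow(strainRatioByGroupDay) == ng,
        length(readerThresholds) == 2L)
    structure(list(nPerGroup = as.integer(nPerGroup), days = days,
        examDays = examDays, elastoDays = elastoDays, growth = growth,
        schedules = schedules, kinetics = kinetics, law = law,
        imageDim = as.integer(imageDim), frameRate = frameRate,
        cineNoiseSd = cineNoiseSd, gain = gain, background = background,
        rhoByGroupExam = rhoByGroupExam, rhoCv = rhoCv,
        necroticByGroupExam = necroticByGroupExam, necroticSd = necroticSd,
        strainRatioByGroupDay = strainRatioByGroupDay,
        strainRatioCv = strainRatioCv, strainNoiseSd = strainNoiseSd,
        padRows = as.integer(padRows),
        readerThresholds = readerThresholds),
        class = "mbceusStudyConfig")
}

#' Simulate a full study data set to disk
#'
#' Generates and writes everything [runStudy()] consumes: the cohort
#' growth table (CSV), one cine loop (multi-page TIFF + JSON sidecar) and
#' tumour ROI mask per animal and contrast-exam day, and one replicate
#' strain set per animal and elastography day. A pure function of
#' (config, seed): rerunning with the same arguments writes byte-identical
#' files.
#'
#' @param config from [studyConfig()].
#' @param seed integer master seed.
#' @param outDir output directory (created if absent).
#' @return Invisibly, \code{outDir}.
#' @export
simulateStudy <- function(config = studyConfig(), seed = 1L, outDir) {
    stopifnot(inherits(config, "mbceusStudyConfig"))
    dir.create(file.path(outDir, "cines"), recursive = TRUE,
        showWarnings = FALSE)
    dir.create(file.path(outDir, "strain"), recursive = TRUE,
        showWarnings = FALSE)
    ng <- length(config$schedules)
    # draw the whole per-animal manifest under the master seed
    man <- withSeed(seed, {
        cohortSeed <- sample.int(2^31 - 1, 1)
        rows <- list()
        for (g in seq_len(ng)) for (k in seq_len(config$nPerGroup[g])) {
            gid <- config$schedules[[g]]@groupId
            rows[[length(rows) + 1L]] <- data.frame(
                animal = sprintf("g%d_a%02d", gid, k), group = gid,
                rho1 = config$rhoByGroupExam[g, 1] *
                    exp(stats::rnorm(1, sd = config$rhoCv)),
                rho2 = config$rhoByGroupExam[g, 2] *
                    exp(stats::rnorm(1, sd = config$rhoCv)),
                nec1 = min(0.6, max(0, config$necroticByGroupExam[g, 1] +
                    stats::rnorm(1, sd = config$necroticSd))),
                nec2 = min(0.6, max(0, config$necroticByGroupExam[g, 2] +
                    stats::rnorm(1, sd = config$necroticSd))),
                ratio1 = config$strainRatioByGroupDay[g, 1] *
                    exp(stats::rnorm(1, sd = config$strainRatioCv)),
                ratio2 = config$strainRatioByGroupDay[g, 2] *
                    exp(stats::rnorm(1, sd = config$strainRatioCv)),
                cineSeed1 = sample.int(2^31 - 1, 1),
                cineSeed2 = sample.int(2^31 - 1, 1),
                strainSeed1 = sample.int(2^31 - 1, 1),
                strainSeed2 = sample.int(2^31 - 1, 1))
        }
        list(cohortSeed = cohortSeed,
            animals = do.call(rbind, c(rows, list(make.row.names = FALSE))))
    })
    cohort <- simulateGrowthCohort(config$growth, config$schedules,
        config$nPerGroup, days = config$days, seed = man$cohortSeed)
    writeCohort(cohort, file.path(outDir, "cohort.csv"))
    for (i in seq_len(nrow(man$animals))) {
        a <- man$animals[i, ]
        for (e in 1:2) {
            day <- config$examDays[e]
            ph <- tumorPhantom(dim = config$imageDim,
                necroticFraction = a[[paste0("nec", e)]],
                rho = a[[paste0("rho", e)]])
            cine <- renderCine(ph, config$kinetics, config$law,
                noiseSd = config$cineNoiseSd,
                seed = a[[paste0("cineSeed", e)]],
                frameRate = config$frameRate, gain = config$gain,
                background = config$background)
            base <- file.path(outDir, "cines",
                sprintf("cine_%s_day%02d", a$animal, day))
            writeCine(cine, paste0(base, ".tif"), paste0(base, ".json"))
            writeMask(tumorMask(ph), file.path(outDir, "cines",
                sprintf("roi_%s_day%02d.tif", a$animal, day)))
        }
        phStrain <- tumorPhantom(dim = config$imageDim,
            padRows = config$padRows)
        for (e in 1:2) {
            day <- config$elastoDays[e]
            sp <- simulateStrainPair(a[[paste0("ratio", e)]],
                noiseSd = config$strainNoiseSd, phantom = phStrain,
                seed = a[[paste0("strainSeed", e)]])
            writeStrainPair(sp, file.path(outDir, "strain",
                sprintf("strain_%s_day%02d", a$animal, day)))
        }
    }
    invisible(outDir)
}

# group-wise median (range) rows for one endpoint/timepoint
summarizeEndpoint <- function(df, endpoint, timepoint) {
    out <- lapply(split(df$value, df$group), function(v)
        groupSummary(v[is.finite(v)]))
    groups <- as.integer(names(out))
    cbind(data.frame(endpoint = endpoint, timepoint = timepoint,
        group = groups), do.call(rbind, c(out, list(make.row.names = FALSE))))
}

# all-groups Kruskal-Wallis plus pairwise exact Mann-Whitney rows
testEndpoint <- function(df, endpoint, timepoint) {
    vals <- split(df$value[is.finite(df$value)],
        df$group[is.finite(df$value)])
    vals <- vals[vapply(vals, length, integer(1)) > 0L]
    rows <- list()
    if (length(vals) >= 2L && all(vapply(vals, length, integer(1)) >= 2L)) {
        kw <- kruskalWallis(vals)
        rows[[1L]] <- data.frame(endpoint = endpoint,
            timepoint = timepoint, comparison = "all-groups",
            method = kw@method, statistic = kw@statistic, p = kw@pValue)
        gs <- names(vals)
        for (i in seq_along(gs)) for (j in seq_along(gs)) if (i < j) {
            mw <- mannWhitney(vals[[i]], vals[[j]])
            rows[[length(rows) + 1L]] <- data.frame(endpoint = endpoint,
                timepoint = timepoint,
                comparison = sprintf("g%s-vs-g%s", gs[i], gs[j]),
                method = mw@method, statistic = mw@statistic,
                p = mw@pValue)
        }
    }
    if (length(rows))
        do.call(rbind, c(rows, list(make.row.names = FALSE)))
    else NULL
}

#' Run the full quantification pipeline over a simulated or measured study
#'
#' Reads the cohort table and the per-animal cine and strain files from
#' \code{dataDir}, computes per-animal endpoints -- volumes at each
#' measurement day, percentage growth deltas (end of study vs day 0 and vs
#' the interruption day), dTE per contrast exam and its delta, the
#' two-reader perfusion consensus per exam, and the triplicate-mean
#' elasticity ratio per elastography day with its delta -- then summarizes
#' each endpoint as group median (range) and tests group differences
#' (Kruskal-Wallis across all groups; exact Mann-Whitney pairwise).
#' Percentage deltas are computed per animal and then summarized
#' (median-of-deltas, never delta-of-medians). Missing animal/day records
#' are an error naming the gaps; nothing is imputed. When any group has
#' fewer than two animals, summaries are still produced but tests are
#' skipped with a warning.
#'
#' @param dataDir directory written by [simulateStudy()] (or arranged the
#'   same way).
#' @param config the [studyConfig()] used for acquisition conventions
#'   (exam days, reader thresholds, quantification windows are taken from
#'   here, not re-estimated).
#' @param outDir if non-NULL, \code{report.csv} and \code{summary.json}
#'   are written there.
#' @return A list with components \code{perAnimal} (long data.frame of
#'   per-animal endpoint values), \code{report} (group summaries) and
#'   \code{tests} (test table; NULL when skipped).
#' @export
runStudy <- function(dataDir, config = studyConfig(), outDir = NULL) {
    stopifnot(inherits(config, "mbceusStudyConfig"))
    cohort <- readCohort(file.path(dataDir, "cohort.csv"))
    animals <- unique(cohort[, c("animal_id", "group")])
    # completeness check: every animal at every measurement day
    gaps <- character()
    for (i in seq_len(nrow(animals))) {
        have <- cohort$day[cohort$animal_id == animals$animal_id[i]]
        miss <- setdiff(config$days, have)
        if (length(miss))
            gaps <- c(gaps, sprintf("%s: day %s", animals$animal_id[i],
                paste(miss, collapse = ",")))
    }
    if (length(gaps))
        stopf("missing cohort records (no imputation): %s",
            paste(gaps, collapse = "; "))
    cohort$volume <- tumorVolume(cohort$height_mm, cohort$width_mm,
        cohort$thickness_mm)

    per <- list()
    addRows <- function(df) per[[length(per) + 1L]] <<- df
    for (d in config$days)
        addRows(data.frame(animal = cohort$animal_id[cohort$day == d],
            group = cohort$group[cohort$day == d], endpoint = "volume",
            timepoint = sprintf("day%d", d),
            value = cohort$volume[cohort$day == d]))
    vol <- function(aid, d)
        cohort$volume[cohort$animal_id == aid & cohort$day == d]
    d0 <- min(config$days); dEnd <- max(config$days)
    dStop <- config$examDays[1]
    for (i in seq_len(nrow(animals))) {
        aid <- animals$animal_id[i]; g <- animals$group[i]
        addRows(data.frame(animal = aid, group = g,
            endpoint = "volume_delta",
            timepoint = sprintf("day%d_vs_day%d", dEnd, d0),
            value = percentDelta(vol(aid, d0), vol(aid, dEnd))))
        addRows(data.frame(animal = aid, group = g,
            endpoint = "volume_delta",
            timepoint = sprintf("day%d_vs_day%d", dEnd, dStop),
            value = percentDelta(vol(aid, dStop), vol(aid, dEnd))))
    }

    # contrast exams: dTE and perfusion consensus
    dteVals <- matrix(NA_real_, nrow(animals), 2L)
    for (i in seq_len(nrow(animals))) {
        aid <- animals$animal_id[i]; g <- animals$group[i]
        for (e in 1:2) {
            day <- config$examDays[e]
            base <- file.path(dataDir, "cines",
                sprintf("cine_%s_day%02d", aid, day))
            roiPath <- file.path(dataDir, "cines",
                sprintf("roi_%s_day%02d.tif", aid, day))
            if (!file.exists(paste0(base, ".tif")) ||
                !file.exists(roiPath))
                stopf("missing exam files for %s day %d", aid, day)
            cine <- readCine(paste0(base, ".tif"), paste0(base, ".json"))
            roi <- readMask(roiPath)
            tic <- roiTIC(cine, roi)
            res <- computeDTE(tic)
            dteVals[i, e] <- dte(res)
            addRows(data.frame(animal = aid, group = g, endpoint = "dte",
                timepoint = sprintf("day%d", day), value = dte(res)))
            pk <- peakEnhancementFrame(tic)
            E <- linearize(frames(cine)[, , pk], compressionLawOf(cine))
            readings <- lapply(seq_along(config$readerThresholds),
                function(r) perfusionReading(
                    nonEnhancedFraction(E, roi,
                        config$readerThresholds[r]),
                    readerId = LETTERS[r]))
            addRows(data.frame(animal = aid, group = g,
                endpoint = "perfusion_nonenhanced",
                timepoint = sprintf("day%d", day),
                value = consensusReading(readings[[1]], readings[[2]])))
        }
        dteDelta <- if (dteVals[i, 1] > 0)
            percentDelta(dteVals[i, 1], dteVals[i, 2]) else NA_real_
        if (is.na(dteDelta))
            warning(sprintf(
                "animal %s: non-positive first-exam dTE, delta undefined",
                aid))
        addRows(data.frame(animal = aid, group = g,
            endpoint = "dte_delta",
            timepoint = sprintf("day%d_vs_day%d", config$examDays[2],
                config$examDays[1]), value = dteDelta))
    }

    # elastography
    for (i in seq_len(nrow(animals))) {
        aid <- animals$animal_id[i]; g <- animals$group[i]
        ratios <- numeric(2)
        for (e in 1:2) {
            day <- config$elastoDays[e]
            prefix <- file.path(dataDir, "strain",
                sprintf("strain_%s_day%02d", aid, day))
            if (!file.exists(paste0(prefix, ".tif")))
                stopf("missing strain files for %s day %d", aid, day)
            sp <- readStrainPair(prefix)
            reps <- strainRatio(sp)
            ratios[e] <- meanRatio(triplicateMean(reps))
            addRows(data.frame(animal = aid, group = g,
                endpoint = "elasticity", timepoint = sprintf("day%d", day),
                value = ratios[e]))
        }
        addRows(data.frame(animal = aid, group = g,
            endpoint = "elasticity_delta",
            timepoint = sprintf("day%d_vs_day%d", config$elastoDays[2],
                config$elastoDays[1]),
            value = percentDelta(ratios[1], ratios[2])))
    }

    perAnimal <- do.call(rbind, c(per, list(make.row.names = FALSE)))
    eps <- unique(perAnimal[, c("endpoint", "timepoint")])
    report <- do.call(rbind, lapply(seq_len(nrow(eps)), function(i) {
        sel <- perAnimal$endpoint == eps$endpoint[i] &
            perAnimal$timepoint == eps$timepoint[i]
        summarizeEndpoint(perAnimal[sel, ], eps$endpoint[i],
            eps$timepoint[i])
    }))
    nByGroup <- table(animals$group)
    tests <- NULL
    if (length(nByGroup) >= 2L && all(nByGroup >= 2L)) {
        tests <- do.call(rbind, lapply(seq_len(nrow(eps)), function(i) {
            sel <- perAnimal$endpoint == eps$endpoint[i] &
                perAnimal$timepoint == eps$timepoint[i]
            testEndpoint(perAnimal[sel, ], eps$endpoint[i],
                eps$timepoint[i])
        }))
    } else {
        warning("fewer than two animals in a group: tests skipped")
    }
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(report, file.path(outDir, "report.csv"),
            row.names = FALSE, quote = FALSE)
        jsonlite::write_json(list(per_animal = perAnimal,
            summaries = report, tests = tests),
            file.path(outDir, "summary.json"), auto_unbox = TRUE,
            digits = NA, pretty = TRUE)
    }
    list(perAnimal = perAnimal, report = report, tests = tests)
}
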