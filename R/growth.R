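#' Simulate a xenograft growth cohort
#'
#' Per-animal tumour-diameter trajectories under the study's treatment
#' schedules. Volumes follow day-wise piecewise-exponential growth: the
#' on-drug rate while dosed, the untreated rate off drug, and the untreated
#' rate times \code{reboundMultiplier} after a permanent stop (days beyond
#' the last scheduled drug day of a non-empty schedule). Animal-level
#' lognormal noise perturbs the baseline volume (\code{animalNoiseSd}) and
#' the growth-rate multiplier (\code{rateNoiseSd}). Volumes are reported as
#' (height, width, thickness) triples with a fixed anisotropy of
#' (1.1, 1, 1/1.1) about the cube root, so that
#' height x width x thickness / 2 recovers the volume exactly.
#'
#' @param gp a [GrowthParams-class].
#' @param schedules list of [TreatmentSchedule-class], one per group.
#' @param nPerGroup integer vector of animals per group (each >= 1).
#' @param days measurement days; default \code{c(0, 5, 9, 11, 13)}.
#' @param seed integer seed; the table is a pure function of
#'   (parameters, seed).
#' @return A data.frame with columns \code{animal_id, group, day,
#'   height_mm, width_mm, thickness_mm}.
#' @examples
#' tab <- simulateGrowthCohort(growthParams(), defaultSchedules(),
#'     nPerGroup = c(4, 6, 4), seed = 1)
#' head(tab)
#' @seealso [tumorVolume()], [runStudy()]
#' @export
simulateGrowthCohort <- function(gp, schedules, nPerGroup,
        days = c(0, 5, 9, 11, 13), seed = 1L) {
    stopifnot(is(gp, "GrowthParams"))
    validObject(gp)
    if (!length(schedules))
        stopf("at least one treatment schedule is required")
    if (!all(vapply(schedules, is, logical(1), "TreatmentSchedule")))
        stopf("schedules must be TreatmentSchedule objects")
    if (length(nPerGroup) != length(schedules) || any(nPerGroup < 1L))
        stopf("nPerGroup must give >= 1 animal for each schedule")
    days <- sort(unique(as.integer(days)))
    maxDay <- max(days)
    withSeed(seed, {
        rows <- list()
        aid <- 0L
        for (g in seq_along(schedules)) {
            sched <- schedules[[g]]
            onDays <- sched@drugOnDays
            stopDay <- if (length(onDays)) max(onDays) else NA_integer_
            for (k in seq_len(nPerGroup[g])) {
                aid <- aid + 1L
                v0 <- gp@baselineVolume *
                    exp(stats::rnorm(1, sd = gp@animalNoiseSd))
                rateMult <- exp(stats::rnorm(1, sd = gp@rateNoiseSd))
                # daily log-growth increments from day d to d+1
                dailyRate <- vapply(seq_len(maxDay) - 1L, function(d) {
                    if (d %in% onDays) gp@growthRateOnDrug
                    else if (!is.na(stopDay) && d > stopDay)
                        gp@growthRateUntreated * gp@reboundMultiplier
                    else gp@growthRateUntreated
                }, numeric(1)) * rateMult
                logV <- log(v0) + c(0, cumsum(dailyRate))
                vols <- exp(logV[days + 1L])
                base <- (2 * vols)^(1 / 3)
                rows[[aid]] <- data.frame(
                    animal_id = sprintf("g%d_a%02d", sched@groupId, k),
                    group = sched@groupId, day = days,
                    height_mm = 1.1 * base, width_mm = base,
                    thickness_mm = base / 1.1)
            }
        }
        do.call(rbind, c(rows, list(make.row.names = FALSE)))
    })
}
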