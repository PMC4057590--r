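#' Write a cine loop as multi-page TIFF plus JSON sidecar
#'
#' Frames are stored as 8-bit grayscale pages (display levels preserved
#' exactly); acquisition metadata -- frame rate, frame timestamps, flash
#' interval, compression law, pixel size -- goes to the JSON sidecar.
#'
#' @param cine a [CineLoop-class].
#' @param tifPath,jsonPath output paths.
#' @return Invisibly, \code{tifPath}.
#' @seealso [readCine()]
#' @export
writeCine <- function(cine, tifPath, jsonPath = sub("\\.tiff?$", ".json",
        tifPath)) {
    stopifnot(is(cine, "CineLoop"))
    L1 <- cine@law@levels - 1L
    pages <- lapply(seq_len(dim(cine@frames)[3]),
        function(i) cine@frames[, , i] / L1)
    tiff::writeTIFF(pages, tifPath, bits.per.sample = 8L)
    meta <- list(
        frame_rate_hz = cine@frameRate,
        frame_times_s = cine@times,
        flash_onset_s = if (length(cine@flash)) cine@flash[1] else NULL,
        flash_duration_s = if (length(cine@flash)) diff(cine@flash) else NULL,
        compression_law = list(dr_db = cine@law@drDb, e_ref = cine@law@eRef,
            levels = cine@law@levels),
        pixel_size_mm = cine@pixelSizeMm)
    jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))], jsonPath,
        auto_unbox = TRUE, digits = NA)
    invisible(tifPath)
}

#' Read a cine loop written by [writeCine()]
#'
#' @param tifPath,jsonPath paths of the multi-page TIFF and its JSON
#'   sidecar.
#' @return A [CineLoop-class].
#' @export
readCine <- function(tifPath, jsonPath = sub("\\.tiff?$", ".json",
        tifPath)) {
    meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
    law <- compressionLaw(drDb = meta$compression_law$dr_db,
        eRef = meta$compression_law$e_ref,
        levels = if (!is.null(meta$compression_law$levels))
            meta$compression_law$levels else 256L)
    pages <- tiff::readTIFF(tifPath, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    L1 <- law@levels - 1L
    D <- array(0L, dim = c(dim(pages[[1]])[1:2], length(pages)))
    for (i in seq_along(pages)) {
        p <- pages[[i]]
        if (length(dim(p)) > 2L) p <- p[, , 1]   # tolerate grey+alpha
        D[, , i] <- as.integer(round(p * L1))
    }
    times <- meta$frame_times_s
    if (is.null(times))
        times <- (seq_len(length(pages)) - 1L) / meta$frame_rate_hz
    flash <- if (!is.null(meta$flash_onset_s))
        c(meta$flash_onset_s, meta$flash_onset_s + meta$flash_duration_s)
    else numeric()
    new("CineLoop", frames = D, times = as.numeric(times),
        frameRate = meta$frame_rate_hz, flash = as.numeric(flash),
        law = law, pixelSizeMm = if (!is.null(meta$pixel_size_mm))
            meta$pixel_size_mm else NA_real_)
}

#' Write / read a binary mask as single-page 8-bit TIFF (0/255)
#'
#' @param mask logical matrix.
#' @param path file path.
#' @return \code{writeMask}: invisibly, \code{path}; \code{readMask}: a
#'   logical matrix.
#' @export
writeMask <- function(mask, path) {
    assertMask(mask)
    tiff::writeTIFF((mask * 1), path, bits.per.sample = 8L)
    invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) > 2L) m <- m[, , 1]
    m > 0.5
}

#' Write / read replicate strain images with masks
#'
#' Strain images are stored as 32-bit float TIFF pages scaled into
#' \code{[0, 1]}; the scale factor and replicate count go to a JSON
#' sidecar, and the tumour and pad masks to companion mask TIFFs.
#'
#' @param pair a [StrainPair-class].
#' @param prefix path prefix; files \code{<prefix>.tif},
#'   \code{<prefix>.json}, \code{<prefix>_tumor.tif},
#'   \code{<prefix>_pad.tif} are written.
#' @return \code{writeStrainPair}: invisibly, the prefix;
#'   \code{readStrainPair}: a [StrainPair-class].
#' @export
writeStrainPair <- function(pair, prefix) {
    stopifnot(is(pair, "StrainPair"))
    hi <- max(vapply(pair@strain, max, numeric(1)), 0)
    scale <- if (hi > 0) 2 * hi else 1
    tiff::writeTIFF(lapply(pair@strain, function(s) s / scale),
        paste0(prefix, ".tif"), bits.per.sample = 32L)
    jsonlite::write_json(list(strain_scale = scale,
        n_replicates = length(pair@strain)), paste0(prefix, ".json"),
        auto_unbox = TRUE, digits = NA)
    writeMask(pair@tumorMask, paste0(prefix, "_tumor.tif"))
    writeMask(pair@padMask, paste0(prefix, "_pad.tif"))
    invisible(prefix)
}

#' @rdname writeStrainPair
#' @export
readStrainPair <- function(prefix) {
    meta <- jsonlite::read_json(paste0(prefix, ".json"),
        simplifyVector = TRUE)
    pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    new("StrainPair",
        strain = lapply(pages, function(p) {
            if (length(dim(p)) > 2L) p <- p[, , 1]
            p * meta$strain_scale
        }),
        tumorMask = readMask(paste0(prefix, "_tumor.tif")),
        padMask = readMask(paste0(prefix, "_pad.tif")))
}

#' Write / read a cohort growth table as CSV
#'
#' Columns: \code{animal_id, group, day, height_mm, width_mm,
#' thickness_mm}.
#'
#' @param tab data.frame from [simulateGrowthCohort()].
#' @param path CSV path.
#' @return \code{writeCohort}: invisibly, \code{path};
#'   \code{readCohort}: the validated data.frame.
#' @export
writeCohort <- function(tab, path) {
    need <- c("animal_id", "group", "day", "height_mm", "width_mm",
        "thickness_mm")
    if (!all(need %in% names(tab)))
        stopf("cohort table must have columns %s",
            paste(need, collapse = ", "))
    utils::write.csv(tab[, need], path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("animal_id", "group", "day", "height_mm", "width_mm",
        "thickness_mm")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stopf("cohort CSV lacks columns: %s", paste(miss, collapse = ", "))
    tab
}
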