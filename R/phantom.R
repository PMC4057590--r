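#' Build a digital tumour phantom
#'
#' Constructs a circular tumour region centred in the upper part of the
#' image, a necrotic (non-perfused) subregion holding exactly
#' \code{round(necroticFraction * n_tumour)} of the tumour pixels (those
#' nearest the tumour centre, emulating central necrosis), an optional
#' reference-pad strip along the bottom rows, and a receptor-density map
#' equal to \code{rho} on perfused tumour pixels and zero elsewhere.
#'
#' @param dim image dimensions, \code{c(rows, cols)} pixels.
#' @param tumorRadius tumour radius in pixels; default scales with image
#'   size.
#' @param necroticFraction fraction of tumour pixels that are necrotic,
#'   in \code{[0, 1]}.
#' @param rho receptor density on perfused tumour pixels (>= 0).
#' @param padRows number of bottom rows forming the reference pad; 0 for
#'   none. The pad never overlaps the tumour (an error otherwise).
#' @return A [TumorPhantom-class] object.
#' @examples
#' ph <- tumorPhantom(dim = c(48, 48), necroticFraction = 0.3)
#' sum(necroticMask(ph)) / sum(tumorMask(ph))
#' @export
tumorPhantom <- function(dim = c(64L, 64L), tumorRadius = NULL,
        necroticFraction = 0, rho = 1, padRows = 0L) {
    dim <- as.integer(dim)
    if (length(dim) != 2L || any(dim < 8L))
        stopf("dim must be two integers >= 8")
    if (necroticFraction < 0 || necroticFraction > 1)
        stopf("necroticFraction must lie in [0, 1]")
    if (rho < 0) stopf("rho must be non-negative")
    if (is.null(tumorRadius)) tumorRadius <- min(dim) * 0.3
    nr <- dim[1]; nc <- dim[2]
    # tumour centred horizontally, above any pad strip
    cr <- (nr - padRows) / 2 + 0.5
    cc <- nc / 2 + 0.5
    d2 <- outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, "+")
    tumor <- d2 <= tumorRadius^2
    if (!any(tumor)) stopf("tumour region is empty; increase tumorRadius")
    necrotic <- matrix(FALSE, nr, nc)
    nNecro <- roundHalfUp(necroticFraction * sum(tumor))
    if (nNecro > 0) {
        idx <- which(tumor)
        necrotic[idx[order(d2[idx])[seq_len(nNecro)]]] <- TRUE
    }
    pad <- matrix(FALSE, nr, nc)
    if (padRows > 0L) {
        pad[(nr - padRows + 1L):nr, ] <- TRUE
        if (any(pad & tumor))
            stopf("pad strip overlaps the tumour; reduce padRows or tumorRadius")
    }
    rmap <- matrix(0, nr, nc)
    rmap[tumor & !necrotic] <- rho
    new("TumorPhantom", tumorMask = tumor, necroticMask = necrotic,
        padMask = pad, receptorMap = rmap)
}
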