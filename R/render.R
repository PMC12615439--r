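#' Render a lambda stack as a two-color combined spectral image
#'
#' Deterministic color composite of a 32-channel spectral image in the
#' convention used for combined spectral renders of collagen-rich tissue:
#' the SHG-band integral is mapped to purple (equal red and blue) and the
#' TPEF-band integral to blue, so collagen fibers appear purple against blue
#' cellular fluorescence. Each band is rescaled to `[0, 1]` by its own
#' maximum before coloring, which makes the render invariant to global
#' intensity scaling; channels are clipped to `[0, 1]`. An all-zero stack
#' renders as black.
#'
#' @param stack A [lambda_stack()].
#' @return An `H x W x 3` RGB array in `[0, 1]`.
#' @export
combine_spectral_image <- function(stack) {
  stopifnot(inherits(stack, "lambda_stack"))
  shg <- rescale_max(band_integrate(stack, stack$meta$shg_band))
  tpef <- rescale_max(band_integrate(stack, stack$meta$tpef_band))
  rgb <- array(0, dim = c(dim(shg), 3))
  rgb[, , 1] <- shg
  rgb[, , 3] <- pmin(shg + tpef, 1)
  rgb
}

#' Overlay a two-channel TPEF/SHG image in red/green
#'
#' Standard two-channel false-color overlay: SHG is color-coded green and
#' TPEF red (blue stays zero), so structures strong in both -- collagen
#' fibers that also emit weak broadband fluorescence -- appear yellow.
#' Each channel is rescaled by its own maximum.
#'
#' @param img A [two_channel_image()].
#' @return An `H x W x 3` RGB array in `[0, 1]`.
#' @export
overlay_tpef_shg <- function(img) {
  stopifnot(inherits(img, "two_channel_image"))
  rgb <- array(0, dim = c(dim(img$shg), 3))
  rgb[, , 1] <- rescale_max(img$tpef)
  rgb[, , 2] <- rescale_max(img$shg)
  rgb
}

# max-rescale to [0,1]; all-zero input stays zero (rendered black, no error)
#' @keywords internal
rescale_max <- function(x) {
  m <- max(x)
  if (m > 0) x / m else x
}

#' Write an RGB render to an 8-bit PNG
#'
#' @param rgb `H x W x 3` array in `[0, 1]`, as returned by
#'   [combine_spectral_image()] or [overlay_tpef_shg()].
#' @param path Output PNG path.
#' @export
write_render_png <- function(rgb, path) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  png::writePNG(pmin(pmax(rgb, 0), 1), target = path)
  invisible(path)
}
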