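#' Lambda stack: a spectrally resolved image
#'
#' The central spectral-imaging object: an `H x W x n_channels` array of
#' non-negative intensities in which each pixel carries a sampled emission
#' spectrum, plus the [wavelength_grid()] labelling the channels and the
#' [acquisition_meta()] describing excitation and detector bands.
#'
#' @param pixels Numeric `H x W x C` array, all values `>= 0`.
#' @param grid A [wavelength_grid()] with `n_channels == dim(pixels)[3]`.
#' @param meta An [acquisition_meta()].
#' @return An object of class `lambda_stack`.
#' @export
lambda_stack <- function(pixels, grid = wavelength_grid(),
                         meta = acquisition_meta()) {
  stopifnot(inherits(grid, "wavelength_grid"),
            inherits(meta, "acquisition_meta"))
  if (!is.array(pixels) || length(dim(pixels)) != 3) {
    stop("`pixels` must be an H x W x C array", call. = FALSE)
  }
  if (dim(pixels)[3] != grid$n_channels) {
    stop("stack has ", dim(pixels)[3], " channels but grid declares ",
         grid$n_channels, call. = FALSE)
  }
  if (any(pixels < 0)) stop("intensities must be non-negative", call. = FALSE)
  structure(list(pixels = pixels, grid = grid, meta = meta),
            class = "lambda_stack")
}

#' Two-channel TPEF/SHG image
#'
#' The multichannel acquisition mode: one detector collects the narrow SHG
#' band (fibrillar collagen), the other the broad TPEF band (NADH, FAD and
#' other endogenous fluorophores).
#'
#' @param shg,tpef Non-negative numeric matrices of identical shape.
#' @param meta An [acquisition_meta()].
#' @return An object of class `two_channel_image`.
#' @export
two_channel_image <- function(shg, tpef, meta = acquisition_meta()) {
  stopifnot(is.matrix(shg), is.matrix(tpef), identical(dim(shg), dim(tpef)),
            inherits(meta, "acquisition_meta"))
  if (any(shg < 0) || any(tpef < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  structure(list(shg = shg, tpef = tpef, meta = meta),
            class = "two_channel_image")
}

# Resolve a region of interest to a logical H x W mask.
# Accepts NULL (whole image), a logical matrix, or c(row1, row2, col1, col2).
#' @keywords internal
as_roi_mask <- function(roi, dims) {
  if (is.null(roi)) {
    return(matrix(TRUE, dims[1], dims[2]))
  }
  if (is.logical(roi) && is.matrix(roi)) {
    if (!identical(dim(roi), as.integer(dims[1:2]))) {
      stop("ROI mask shape does not match the image", call. = FALSE)
    }
    if (!any(roi)) stop("ROI is empty", call. = FALSE)
    return(roi)
  }
  if (is.numeric(roi) && length(roi) == 4) {
    r <- as.integer(roi)
    if (r[1] < 1 || r[2] > dims[1] || r[3] < 1 || r[4] > dims[2] ||
        r[1] > r[2] || r[3] > r[4]) {
      stop("ROI bounds out of range or empty", call. = FALSE)
    }
    m <- matrix(FALSE, dims[1], dims[2])
    m[r[1]:r[2], r[3]:r[4]] <- TRUE
    return(m)
  }
  stop("ROI must be NULL, a logical mask, or c(row1, row2, col1, col2)",
       call. = FALSE)
}

#' Mean emission spectrum over a region of interest
#'
#' Averages the per-pixel spectra of a lambda stack over an ROI: intensity at
#' channel `k` is the arithmetic mean of channel `k` over the ROI pixels.
#' A single-pixel ROI therefore returns that pixel's spectrum exactly.
#'
#' @param stack A [lambda_stack()].
#' @param roi `NULL` (whole image), a logical `H x W` mask, or integer bounds
#'   `c(row1, row2, col1, col2)` (inclusive).
#' @return An [emission_spectrum()] (not normalized).
#' @export
roi_mean_spectrum <- function(stack, roi = NULL) {
  stopifnot(inherits(stack, "lambda_stack"))
  d <- dim(stack$pixels)
  mask <- as_roi_mask(roi, d)
  flat <- matrix(stack$pixels, nrow = d[1] * d[2], ncol = d[3])
  means <- colMeans(flat[as.vector(mask), , drop = FALSE])
  emission_spectrum(channel_labels(stack$grid), means)
}

#' Integrate a lambda stack over a wavelength band
#'
#' Sums, per pixel, the channels whose wavelength label lies inside the
#' closed interval `band`. Summing the SHG band (389--419 nm by default)
#' collapses the stack to a collagen-weighted grayscale image; summing
#' disjoint bands that tile the grid reproduces the full-spectrum total.
#'
#' @param stack A [lambda_stack()].
#' @param band Closed wavelength interval `c(lo, hi)` in nm. Must contain at
#'   least one channel label.
#' @return An `H x W` numeric matrix.
#' @export
band_integrate <- function(stack, band) {
  stopifnot(inherits(stack, "lambda_stack"),
            is.numeric(band), length(band) == 2, band[1] <= band[2])
  labels <- channel_labels(stack$grid)
  sel <- labels >= band[1] & labels <= band[2]
  if (!any(sel)) {
    stop(sprintf("band [%g, %g] nm contains no grid channels", band[1], band[2]),
         call. = FALSE)
  }
  rowSums(stack$pixels[, , sel, drop = FALSE], dims = 2)
}

#' @export
print.lambda_stack <- function(x, ...) {
  d <- dim(x$pixels)
  labs <- channel_labels(x$grid)
  cat(sprintf("<lambda_stack> %d x %d pixels, %d channels (%g--%g nm)\n",
              d[1], d[2], d[3], labs[1], labs[length(labs)]))
  invisible(x)
}

#' @export
print.two_channel_image <- function(x, ...) {
  d <- dim(x$shg)
  cat(sprintf("<two_channel_image> %d x %d pixels (SHG + TPEF)\n", d[1], d[2]))
  invisible(x)
}
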