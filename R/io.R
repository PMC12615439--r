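#' Read and write spectral images as multi-page TIFF with a JSON sidecar
#'
#' Lambda stacks are stored as one TIFF page per channel, in ascending
#' wavelength order; two-channel images as two pages (SHG first, then TPEF).
#' Acquisition metadata travels in a JSON sidecar next to the TIFF
#' (`<stem>.json`) holding `kind`, the wavelength grid, excitation and band
#' definitions, the pixel type and an intensity scale.
#'
#' Integer data (all values whole numbers in 0..65535) is written as 16-bit
#' unsigned and round-trips bit-exactly. Other data is written as 32-bit
#' float; because float TIFF pages are stored on a `[0, 1]` scale, the
#' sidecar records `intensity_scale` (the original maximum) and
#' `read_stack()` multiplies it back, so the round trip is exact to float32
#' precision.
#'
#' @param obj A [lambda_stack()] or [two_channel_image()].
#' @param path TIFF file path; the sidecar is written alongside.
#' @return `read_stack()` returns a `lambda_stack` or `two_channel_image`
#'   according to the sidecar's `kind`; `write_stack()` returns `path`
#'   invisibly.
#' @export
write_stack <- function(obj, path) {
  sidecar <- sidecar_path(path)
  if (inherits(obj, "lambda_stack")) {
    pages <- lapply(seq_len(dim(obj$pixels)[3]),
                    function(k) obj$pixels[, , k])
    meta <- list(
      kind = "lambda_stack",
      start_nm = obj$grid$start_nm, step_nm = obj$grid$step_nm,
      n_channels = obj$grid$n_channels,
      excitation_nm = obj$meta$excitation_nm,
      shg_band = obj$meta$shg_band, tpef_band = obj$meta$tpef_band
    )
  } else if (inherits(obj, "two_channel_image")) {
    pages <- list(obj$shg, obj$tpef)
    meta <- list(
      kind = "two_channel", n_channels = 2L,
      excitation_nm = obj$meta$excitation_nm,
      shg_band = obj$meta$shg_band, tpef_band = obj$meta$tpef_band
    )
  } else {
    stop("write_stack() expects a lambda_stack or two_channel_image",
         call. = FALSE)
  }
  vals <- unlist(pages)
  integral <- all(vals == floor(vals)) && max(vals) <= 65535
  if (integral) {
    meta$dtype <- "uint16"
    meta$intensity_scale <- 1
    tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                    bits.per.sample = 16L)
  } else {
    scale <- max(vals, 1e-12)
    meta$dtype <- "float32"
    meta$intensity_scale <- scale
    tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                    bits.per.sample = 32L)
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  sidecar <- sidecar_path(path)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!file.exists(sidecar)) {
    stop("metadata sidecar not found: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  as_is <- identical(meta$dtype, "uint16")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
  if (!is.list(pages)) pages <- list(pages)
  declared <- as.integer(meta$n_channels)
  if (length(pages) != declared) {
    stop(sprintf("format error: %s has %d pages but metadata declares %d",
                 path, length(pages), declared), call. = FALSE)
  }
  scale <- if (as_is) 1 else as.numeric(meta$intensity_scale)
  pages <- lapply(pages, function(p) {
    p <- as.matrix(p) * scale
    storage.mode(p) <- "double"
    p
  })
  acq <- acquisition_meta(excitation_nm = meta$excitation_nm,
                          shg_band = meta$shg_band,
                          tpef_band = meta$tpef_band)
  if (identical(meta$kind, "lambda_stack")) {
    grid <- wavelength_grid(meta$start_nm, meta$step_nm, meta$n_channels)
    px <- array(0, dim = c(dim(pages[[1]]), declared))
    for (k in seq_len(declared)) px[, , k] <- pages[[k]]
    lambda_stack(px, grid, acq)
  } else if (identical(meta$kind, "two_channel")) {
    two_channel_image(pages[[1]], pages[[2]], acq)
  } else {
    stop("unknown stack kind in sidecar: ", meta$kind, call. = FALSE)
  }
}

#' @keywords internal
sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write a binary mask as a PNG image
#'
#' @param mask Logical matrix.
#' @param path Output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1, target = path)
  invisible(path)
}
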