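#' Emission spectrum
#'
#' A paired (wavelength, intensity) record, stored as a tibble with columns
#' `wavelength_nm` and `intensity` so it pipes directly into dplyr/ggplot2.
#' Wavelengths must be strictly increasing and intensities non-negative.
#' The `normalized` attribute records whether the spectrum has been scaled
#' to unit maximum (see [normalize_spectrum()]).
#'
#' @param wavelength_nm Strictly increasing numeric vector (nm).
#' @param intensity Non-negative numeric vector, same length.
#' @param normalized Logical flag; if `TRUE` the maximum intensity must be 1
#'   (within 1e-9).
#' @return A tibble of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength_nm, intensity, normalized = FALSE) {
  stopifnot(
    is.numeric(wavelength_nm), is.numeric(intensity),
    length(wavelength_nm) == length(intensity),
    length(wavelength_nm) >= 1
  )
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (isTRUE(normalized) && abs(max(intensity) - 1) > 1e-9) {
    stop("a spectrum flagged normalized must have unit maximum", call. = FALSE)
  }
  out <- tibble(wavelength_nm = as.numeric(wavelength_nm),
                intensity = as.numeric(intensity))
  attr(out, "normalized") <- isTRUE(normalized)
  class(out) <- c("emission_spectrum", class(out))
  out
}

#' Is a spectrum flagged as normalized?
#' @param s An [emission_spectrum()].
#' @return Logical scalar.
#' @export
is_normalized <- function(s) isTRUE(attr(s, "normalized"))

#' Scale a spectrum to unit maximum
#'
#' Divides intensities by their maximum so the strongest emission peak equals
#' 1, the convention used when comparing spectra whose absolute detector
#' units are arbitrary. Idempotent and invariant to positive rescaling of the
#' input.
#'
#' @param s An [emission_spectrum()] (or a data frame with `wavelength_nm`
#'   and `intensity` columns).
#' @return A normalized `emission_spectrum`.
#' @export
normalize_spectrum <- function(s) {
  s <- as_emission_spectrum(s)
  m <- max(s$intensity)
  if (m <= 0) {
    stop("cannot normalize an all-zero spectrum", call. = FALSE)
  }
  emission_spectrum(s$wavelength_nm, s$intensity / m, normalized = TRUE)
}

#' @keywords internal
as_emission_spectrum <- function(s) {
  if (inherits(s, "emission_spectrum")) return(s)
  if (is.data.frame(s) && all(c("wavelength_nm", "intensity") %in% names(s))) {
    return(emission_spectrum(s$wavelength_nm, s$intensity))
  }
  stop("expected an emission_spectrum or a data frame with columns ",
       "'wavelength_nm' and 'intensity'", call. = FALSE)
}

#' Read / write an emission spectrum as two-column CSV
#'
#' The on-disk format is a CSV with header `wavelength_nm,intensity`.
#' Doubles are written at full precision so a write/read round trip is exact.
#'
#' @param path File path.
#' @return `read_spectrum_csv()` returns an `emission_spectrum`.
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) {
    stop("spectrum file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("failed to parse spectrum CSV ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!all(c("wavelength_nm", "intensity") %in% names(df)) || nrow(df) == 0) {
    stop("malformed spectrum CSV ", path,
         ": need non-empty columns wavelength_nm,intensity", call. = FALSE)
  }
  emission_spectrum(df$wavelength_nm, df$intensity)
}

#' @rdname read_spectrum_csv
#' @param s An [emission_spectrum()].
#' @export
write_spectrum_csv <- function(s, path) {
  s <- as_emission_spectrum(s)
  readr::write_csv(tibble(wavelength_nm = s$wavelength_nm,
                          intensity = s$intensity), path)
  invisible(path)
}

#' @method autoplot emission_spectrum
#' @export
autoplot.emission_spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$wavelength_nm, y = .data$intensity)) +
    geom_line() +
    labs(x = "Emission wavelength (nm)",
         y = if (is_normalized(object)) "Normalized intensity" else
           "Intensity (a.u.)") +
    theme_minimal()
}
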