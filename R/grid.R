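#' Uniform wavelength grid for lambda-mode acquisition
#'
#' A lambda stack samples the emission spectrum on a uniform wavelength grid.
#' Channel `k` (1-based) carries the label `start_nm + (k - 1) * step_nm`;
#' labels are the lower edges of the detection bins. The default grid is the
#' 32-channel, 11-nm acquisition starting at 382 nm used for multiphoton
#' spectral imaging of tissue, under which the channel closest to the
#' 405-nm second-harmonic line is labelled 404 nm.
#'
#' @param start_nm Wavelength label of the first channel (nm), non-negative.
#' @param step_nm Channel spacing (nm), strictly positive.
#' @param n_channels Number of channels, a positive integer.
#' @return An object of class `wavelength_grid`.
#' @examples
#' g <- wavelength_grid()
#' channel_labels(g)[3] # 404
#' @export
wavelength_grid <- function(start_nm = 382, step_nm = 11, n_channels = 32) {
  stopifnot(
    is.numeric(start_nm), length(start_nm) == 1, start_nm >= 0,
    is.numeric(step_nm), length(step_nm) == 1, step_nm > 0,
    is.numeric(n_channels), length(n_channels) == 1, n_channels >= 1,
    n_channels == as.integer(n_channels)
  )
  structure(
    list(start_nm = start_nm, step_nm = step_nm,
         n_channels = as.integer(n_channels)),
    class = "wavelength_grid"
  )
}

#' Channel wavelength labels of a grid
#'
#' @param grid A [wavelength_grid()].
#' @return Numeric vector of length `n_channels`, strictly increasing.
#' @export
channel_labels <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  grid$start_nm + (seq_len(grid$n_channels) - 1) * grid$step_nm
}

#' Locate the grid channel nearest a target wavelength
#'
#' Ties (a target exactly midway between two labels) resolve to the lower
#' channel index, so the result is deterministic.
#'
#' @param grid A [wavelength_grid()].
#' @param target_nm Target wavelength (nm).
#' @return A list with `index` (1-based channel index) and `label_nm`.
#' @examples
#' nearest_channel(wavelength_grid(), 405) # index 3, label 404
#' @export
nearest_channel <- function(grid, target_nm) {
  stopifnot(is.numeric(target_nm), length(target_nm) == 1, is.finite(target_nm))
  labels <- channel_labels(grid)
  k <- which.min(abs(labels - target_nm)) # which.min takes the first = lower
  list(index = k, label_nm = labels[k])
}

#' Acquisition metadata: excitation line and detector bands
#'
#' Captures the fixed optical configuration of a two-mode multiphoton
#' acquisition: the near-infrared excitation wavelength, the narrow
#' second-harmonic-generation (SHG) detector band, and the broad two-photon
#' excited fluorescence (TPEF) band. Defaults describe 810-nm excitation with
#' SHG collected at 389--419 nm and TPEF at 430--716 nm; the SHG emission at
#' half the excitation wavelength (405 nm) falls inside the default SHG band.
#'
#' @param excitation_nm Excitation wavelength (nm), positive.
#' @param shg_band,tpef_band Closed wavelength intervals `c(lo, hi)` in nm,
#'   each within 300--800 nm and mutually non-overlapping.
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(excitation_nm = 810,
                             shg_band = c(389, 419),
                             tpef_band = c(430, 716)) {
  stopifnot(
    is.numeric(excitation_nm), length(excitation_nm) == 1, excitation_nm > 0,
    is.numeric(shg_band), length(shg_band) == 2, shg_band[1] < shg_band[2],
    is.numeric(tpef_band), length(tpef_band) == 2, tpef_band[1] < tpef_band[2],
    all(shg_band >= 300), all(shg_band <= 800),
    all(tpef_band >= 300), all(tpef_band <= 800)
  )
  if (shg_band[2] >= tpef_band[1] && tpef_band[2] >= shg_band[1]) {
    stop("`shg_band` and `tpef_band` must not overlap", call. = FALSE)
  }
  structure(
    list(excitation_nm = excitation_nm,
         shg_band = as.numeric(shg_band), tpef_band = as.numeric(tpef_band)),
    class = "acquisition_meta"
  )
}

#' Second-harmonic emission wavelength
#'
#' SHG is a coherent two-photon scattering process: two excitation photons
#' combine into one photon at exactly half the excitation wavelength, so
#' 810-nm excitation produces SHG at 405 nm.
#'
#' @param x An [acquisition_meta()] object, or a single positive excitation
#'   wavelength in nm.
#' @return The SHG emission wavelength (nm).
#' @examples
#' shg_wavelength(810) # 405
#' @export
shg_wavelength <- function(x) {
  excitation <- if (inherits(x, "acquisition_meta")) x$excitation_nm else x
  if (!is.numeric(excitation) || length(excitation) != 1 ||
      !is.finite(excitation) || excitation <= 0) {
    stop("excitation wavelength must be a single positive number",
         call. = FALSE)
  }
  excitation / 2
}

#' @export
print.wavelength_grid <- function(x, ...) {
  labs <- channel_labels(x)
  cat(sprintf("<wavelength_grid> %d channels, %g-nm step, %g--%g nm\n",
              x$n_channels, x$step_nm, labs[1], labs[length(labs)]))
  invisible(x)
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat(sprintf(
    "<acquisition_meta> excitation %g nm | SHG band %g--%g nm | TPEF band %g--%g nm\n",
    x$excitation_nm, x$shg_band[1], x$shg_band[2],
    x$tpef_band[1], x$tpef_band[2]))
  invisible(x)
}
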