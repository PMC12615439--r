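#' The eight endogenous emission components
#'
#' Emission spectra of collagen-rich brain-tumor tissue under 810-nm
#' two-photon excitation decompose into eight Gaussian components: the
#' narrow collagen SHG line at 405 nm, protein-bound NADH (425 nm), free
#' NADH (475 nm), structural proteins (510 nm), FAD (545 nm), lipopigments
#' (575 nm), and two porphyrin bands (630 and 690 nm). A component set is a
#' tibble with one row per component: nominal center, the tolerance within
#' which the fitted center may move, the initial Gaussian width, and the
#' width bounds. The SHG line is bounded narrow (sigma 4--15 nm, tracking
#' the laser linewidth) while fluorophores are broad (8--60 nm).
#'
#' @return A tibble of class `component_set` with columns `name`,
#'   `center_nm`, `center_tol_nm`, `sigma_init_nm`, `sigma_lo_nm`,
#'   `sigma_hi_nm`.
#' @export
default_components <- function() {
  cs <- tibble(
    name = c("collagen_SHG", "NADH_bound", "NADH_free", "structural_protein",
             "FAD", "lipopigment", "porphyrin_I", "porphyrin_II"),
    center_nm = c(405, 425, 475, 510, 545, 575, 630, 690),
    center_tol_nm = 5,
    sigma_init_nm = c(8, rep(20, 7)),
    sigma_lo_nm = c(4, rep(8, 7)),
    sigma_hi_nm = c(15, rep(60, 7))
  )
  validate_component_set(cs)
}

#' @keywords internal
validate_component_set <- function(cs) {
  stopifnot(is.data.frame(cs),
            all(c("name", "center_nm", "center_tol_nm", "sigma_init_nm",
                  "sigma_lo_nm", "sigma_hi_nm") %in% names(cs)))
  if (any(diff(cs$center_nm) <= 0)) {
    stop("component centers must be strictly increasing", call. = FALSE)
  }
  if (any(cs$center_tol_nm < 0)) {
    stop("center tolerances must be non-negative", call. = FALSE)
  }
  if (any(cs$sigma_lo_nm <= 0) || any(cs$sigma_lo_nm >= cs$sigma_hi_nm)) {
    stop("sigma bounds must satisfy 0 < lo < hi", call. = FALSE)
  }
  class(cs) <- unique(c("component_set", class(cs)))
  cs
}

#' Sum-of-Gaussians emission model
#'
#' Evaluates `sum_j A_j * exp(-(lambda - mu_j)^2 / (2 sigma_j^2))` at the
#' given wavelengths -- the forward model behind both the multi-peak fit and
#' the synthetic phantom spectra.
#'
#' @param amplitude,center_nm,sigma_nm Equal-length numeric vectors of
#'   per-component parameters; all `sigma_nm` must be positive.
#' @param wavelength_nm Wavelengths (nm) at which to evaluate.
#' @return Numeric vector of model intensities.
#' @export
component_model <- function(amplitude, center_nm, sigma_nm, wavelength_nm) {
  stopifnot(length(amplitude) == length(center_nm),
            length(center_nm) == length(sigma_nm))
  if (any(sigma_nm <= 0)) {
    stop("component widths (sigma) must be positive", call. = FALSE)
  }
  if (length(amplitude) == 0) return(rep(0, length(wavelength_nm)))
  d2 <- outer(wavelength_nm, center_nm, "-")^2
  g <- exp(-sweep(d2, 2, 2 * sigma_nm^2, "/"))
  drop(g %*% amplitude)
}

#' Published component ratios for fibrous meningioma tissue
#'
#' The relative amplitude ratios of the eight emission components reported
#' for fibrous meningioma under 810-nm excitation (collagen SHG most
#' abundant, porphyrin II least), in grid (center) order. Used as a
#' realistic mixing vector for synthetic spectra and as the reference point
#' of the fit round-trip checks.
#'
#' @return Named numeric vector of length 8 in component (center) order.
#' @export
fibrous_meningioma_ratios <- function() {
  c(collagen_SHG = 0.952, NADH_bound = 0.105, NADH_free = 0.393,
    structural_protein = 0.502, FAD = 0.199, lipopigment = 0.198,
    porphyrin_I = 0.104, porphyrin_II = 0.015)
}
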