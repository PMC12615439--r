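#' Specification of a synthetic fibrous-tissue phantom
#'
#' Describes a phantom emulating the appearance of fibrous meningioma under
#' label-free multiphoton imaging: curvilinear collagen fiber bundles that
#' emit in the narrow SHG band (with a small broadband TPEF fraction), cells
#' whose cytoplasm carries NADH/FAD/lipopigment fluorescence around a
#' fluorescence-dark nucleus, per-pixel spectra that are non-negative
#' mixtures of the eight Gaussian component bases, and Poisson + Gaussian
#' detection noise. Identical specs (including `seed`) generate bit-identical
#' phantoms.
#'
#' @param height,width Image size in pixels.
#' @param n_fibers Initial number of fiber strokes attempted; the generator
#'   then adds or drops strokes until the collagen mask fraction is within
#'   0.02 of `target_collagen_fraction`.
#' @param fiber_width_px,fiber_width_jitter_px Mean fiber width and its
#'   Gaussian jitter (pixels).
#' @param fiber_orientation Range `c(lo, hi)` in radians from which stroke
#'   headings are drawn uniformly; default the full half-circle `[0, pi)`.
#' @param fiber_intensity SHG amplitude of fiber pixels (normalized
#'   intensity units).
#' @param n_cells Number of cells placed (rejection sampling keeps nuclei
#'   disjoint and, where space allows, off the collagen).
#' @param cell_radius_px,nucleus_radius_px Cell and nucleus radii (pixels);
#'   nucleus must be smaller.
#' @param cytoplasm_amplitudes Named non-negative amplitudes for
#'   `NADH_free`, `NADH_bound`, `FAD`, `lipopigment` in the cytoplasm
#'   annulus.
#' @param collagen_tpef_fraction Fraction of collagen-pixel energy emitted
#'   as broadband TPEF (added to the structural-protein component).
#' @param target_collagen_fraction Desired true collagen mask fraction, in
#'   `[0, 0.95]`.
#' @param poisson_scale Photons per normalized intensity unit for the
#'   Poisson shot-noise stage; 0 disables shot noise. At the default 200,
#'   a unit-intensity fiber pixel has shot-noise SD `1/sqrt(200) ~ 0.07`,
#'   i.e. SNR ~ 13 together with the read noise.
#' @param gaussian_sd Additive Gaussian read-noise SD; negatives clipped at 0.
#' @param seed Integer seed; every stochastic stage derives from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 256, width = 256,
                         n_fibers = 40,
                         fiber_width_px = 3, fiber_width_jitter_px = 1,
                         fiber_orientation = c(0, pi),
                         fiber_intensity = 1,
                         n_cells = 30,
                         cell_radius_px = 9, nucleus_radius_px = 5,
                         cytoplasm_amplitudes = c(NADH_free = 0.4,
                                                  NADH_bound = 0.1,
                                                  FAD = 0.2,
                                                  lipopigment = 0.2),
                         collagen_tpef_fraction = 0.15,
                         target_collagen_fraction = 0.5,
                         poisson_scale = 200, gaussian_sd = 0.02,
                         seed = 1L) {
  stopifnot(height >= 16, width >= 16, n_fibers >= 0,
            fiber_width_px >= 1, fiber_width_jitter_px >= 0,
            length(fiber_orientation) == 2,
            fiber_intensity > 0, n_cells >= 0,
            cell_radius_px > 0, nucleus_radius_px > 0,
            nucleus_radius_px < cell_radius_px,
            all(cytoplasm_amplitudes >= 0),
            poisson_scale >= 0, gaussian_sd >= 0,
            is.numeric(seed), length(seed) == 1)
  if (target_collagen_fraction < 0 || target_collagen_fraction > 0.95) {
    stop("target_collagen_fraction must lie in [0, 0.95]; denser fiber ",
         "packings are not reachable", call. = FALSE)
  }
  need <- c("NADH_free", "NADH_bound", "FAD", "lipopigment")
  if (!all(need %in% names(cytoplasm_amplitudes))) {
    stop("cytoplasm_amplitudes must name ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         n_fibers = as.integer(n_fibers),
         fiber_width_px = fiber_width_px,
         fiber_width_jitter_px = fiber_width_jitter_px,
         fiber_orientation = fiber_orientation,
         fiber_intensity = fiber_intensity,
         n_cells = as.integer(n_cells),
         cell_radius_px = cell_radius_px,
         nucleus_radius_px = nucleus_radius_px,
         cytoplasm_amplitudes = cytoplasm_amplitudes[need],
         collagen_tpef_fraction = collagen_tpef_fraction,
         target_collagen_fraction = target_collagen_fraction,
         poisson_scale = poisson_scale, gaussian_sd = gaussian_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# one random-walk fiber stroke rasterised to a logical mask
#' @keywords internal
fiber_stroke <- function(h, w, orientation, n_steps, curvature_sd = 0.08) {
  r <- runif(1, 1, h)
  c <- runif(1, 1, w)
  theta <- runif(1, orientation[1], orientation[2])
  m <- matrix(FALSE, h, w)
  for (i in seq_len(n_steps)) {
    ri <- round(r); ci <- round(c)
    if (ri < 1 || ri > h || ci < 1 || ci > w) break
    m[ri, ci] <- TRUE
    r <- r + sin(theta)
    c <- c + cos(theta)
    theta <- theta + rnorm(1, 0, curvature_sd)
  }
  m
}

#' Draw collagen fiber bundles
#'
#' Renders smooth curvilinear strokes (random-walk polylines dilated to the
#' fiber width) and keeps adding or retrying strokes until the collagen mask
#' fraction lies within 0.02 of the spec's target. Deterministic for a given
#' seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list: `collagen_mask` (logical) and `shg_abundance` (numeric
#'   matrix; per-fiber intensity variation around `fiber_intensity`).
#' @export
draw_fibers <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, draw_fibers_impl(spec))
}

#' @keywords internal
draw_fibers_impl <- function(spec, mask = NULL, shg = NULL,
                             forbidden = NULL) {
  h <- spec$height; w <- spec$width
  if (is.null(mask)) mask <- matrix(FALSE, h, w)
  if (is.null(shg)) shg <- matrix(0, h, w)
  target <- spec$target_collagen_fraction
  if (target == 0 || spec$n_fibers == 0) {
    if (target > 0.02) {
      stop("invalid spec: positive target collagen fraction but no fibers",
           call. = FALSE)
    }
    return(list(collagen_mask = mask, shg_abundance = shg))
  }
  base_len <- round(0.9 * min(h, w))
  len_factor <- 1
  attempts <- 0
  # stop just above the target so the later nucleus carve-out (nuclei are
  # fluorescence-dark and leave the collagen mask) stays within +/- 0.02
  while (mean(mask) < target - 0.005) {
    attempts <- attempts + 1
    if (attempts > 4000) {
      stop("could not reach the target collagen fraction ", target,
           call. = FALSE)
    }
    width_px <- max(1, round(rnorm(1, spec$fiber_width_px,
                                   spec$fiber_width_jitter_px)))
    n_steps <- max(8, round(base_len * len_factor))
    stroke <- fiber_stroke(h, w, spec$fiber_orientation, n_steps)
    radius <- max(0L, as.integer(floor((width_px - 1) / 2)))
    if (radius > 0 && any(stroke)) {
      brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
      stroke <- matrix(as.numeric(EBImage::dilate(stroke * 1, brush)) > 0.5,
                       h, w)
    }
    if (!is.null(forbidden)) stroke <- stroke & !forbidden
    candidate <- mask | stroke
    if (mean(candidate) > target + 0.015) {
      # overshoot: retry with shorter strokes for finer granularity
      len_factor <- max(0.05, len_factor * 0.7)
      next
    }
    value <- spec$fiber_intensity * runif(1, 0.85, 1.15)
    shg[stroke & !mask] <- value
    mask <- candidate
  }
  list(collagen_mask = mask, shg_abundance = shg)
}

#' Place cells with dark nuclei and fluorescent cytoplasm
#'
#' Places `n_cells` disk-shaped cells by rejection sampling: nuclei are kept
#' mutually disjoint, and placement first tries to keep nuclei off the
#' collagen mask (after a bounded number of rejections the collagen
#' constraint is relaxed so crowded phantoms degrade gracefully). The
#' cytoplasm annulus carries the spec's NADH/FAD/lipopigment abundances with
#' mild per-cell variation; the nucleus interior carries none, so nuclei are
#' fluorescence-dark.
#'
#' @param spec A [phantom_spec()].
#' @param collagen_mask Logical matrix from [draw_fibers()].
#' @return A list: `nucleus_mask` (logical) and `cytoplasm_maps` (named list
#'   of numeric matrices for `NADH_free`, `NADH_bound`, `FAD`,
#'   `lipopigment`).
#' @export
draw_cells <- function(spec, collagen_mask) {
  stopifnot(inherits(spec, "phantom_spec"),
            is.logical(collagen_mask),
            identical(dim(collagen_mask), c(spec$height, spec$width)))
  withr::with_seed(spec$seed + 1L, draw_cells_impl(spec, collagen_mask))
}

#' @keywords internal
draw_cells_impl <- function(spec, collagen_mask) {
  h <- spec$height; w <- spec$width
  nucleus_mask <- matrix(FALSE, h, w)
  comp_names <- names(spec$cytoplasm_amplitudes)
  maps <- setNames(lapply(comp_names, function(x) matrix(0, h, w)), comp_names)
  if (spec$n_cells == 0) {
    return(list(nucleus_mask = nucleus_mask, cytoplasm_maps = maps))
  }
  cr <- spec$cell_radius_px
  nr <- spec$nucleus_radius_px
  # disk offsets relative to the center
  span <- -ceiling(cr):ceiling(cr)
  offs <- expand.grid(dr = span, dc = span)
  d <- sqrt(offs$dr^2 + offs$dc^2)
  nuc_off <- offs[d <= nr, ]
  ann_off <- offs[d > nr & d <= cr, ]
  for (cell in seq_len(spec$n_cells)) {
    placed <- FALSE
    for (try in 1:60) {
      r0 <- round(runif(1, cr + 1, h - cr))
      c0 <- round(runif(1, cr + 1, w - cr))
      nuc_idx <- cbind(r0 + nuc_off$dr, c0 + nuc_off$dc)
      if (any(nucleus_mask[nuc_idx])) next
      if (try <= 40 && any(collagen_mask[nuc_idx])) next
      ann_idx <- cbind(r0 + ann_off$dr, c0 + ann_off$dc)
      nucleus_mask[nuc_idx] <- TRUE
      gain <- runif(1, 0.8, 1.2)
      for (nm in comp_names) {
        maps[[nm]][ann_idx] <- maps[[nm]][ann_idx] +
          gain * spec$cytoplasm_amplitudes[[nm]]
      }
      placed <- TRUE
      break
    }
    # overcrowded fields simply hold fewer cells
    if (!placed) next
  }
  list(nucleus_mask = nucleus_mask, cytoplasm_maps = maps)
}

# noiseless abundance maps + ground truth shared by both render paths
#' @keywords internal
phantom_truth <- function(spec, components = default_components()) {
  fibers <- draw_fibers(spec)
  cells <- draw_cells(spec, fibers$collagen_mask)
  maps <- setNames(
    lapply(components$name, function(x) matrix(0, spec$height, spec$width)),
    components$name
  )
  collagen_mask <- fibers$collagen_mask & !cells$nucleus_mask
  shg_map <- fibers$shg_abundance
  shg_map[cells$nucleus_mask] <- 0
  # nuclei carved out of the collagen can leave the mask short of the
  # target fraction; top up with extra strokes that avoid the nuclei
  if (spec$target_collagen_fraction > 0 &&
      mean(collagen_mask) < spec$target_collagen_fraction - 0.015) {
    topped <- withr::with_seed(
      spec$seed + 3L,
      draw_fibers_impl(spec, mask = collagen_mask, shg = shg_map,
                       forbidden = cells$nucleus_mask)
    )
    collagen_mask <- topped$collagen_mask
    shg_map <- topped$shg_abundance
  }
  maps$collagen_SHG <- shg_map
  maps$structural_protein <- spec$collagen_tpef_fraction * shg_map
  for (nm in names(cells$cytoplasm_maps)) {
    maps[[nm]] <- maps[[nm]] + cells$cytoplasm_maps[[nm]]
  }
  # nuclei are fluorescence-dark: no abundance of any kind inside
  for (nm in names(maps)) maps[[nm]][cells$nucleus_mask] <- 0
  list(
    collagen_mask = collagen_mask,
    nucleus_mask = cells$nucleus_mask,
    abundance_maps = maps,
    target_fraction = spec$target_collagen_fraction,
    true_fraction = mean(collagen_mask)
  )
}

#' @keywords internal
apply_detection_noise <- function(x, poisson_scale, gaussian_sd) {
  if (poisson_scale > 0) {
    x[] <- rpois(length(x), as.vector(x) * poisson_scale) / poisson_scale
  }
  if (gaussian_sd > 0) {
    x <- x + rnorm(length(x), 0, gaussian_sd)
  }
  pmax(x, 0)
}

#' Render a phantom as a 32-channel lambda stack
#'
#' Each pixel's spectrum is the non-negative mixture of the eight Gaussian
#' component bases (centers and default widths shared with
#' [default_components()]) weighted by that pixel's abundances, sampled at
#' the 32 channel labels; Poisson shot noise and additive Gaussian read
#' noise are then applied and negatives clipped at zero.
#'
#' @param spec A [phantom_spec()].
#' @param grid,meta Acquisition geometry (defaults: the 382--714 nm
#'   32-channel grid, 810-nm excitation).
#' @return A list: `stack` (a [lambda_stack()]) and `truth` (list with
#'   `collagen_mask`, `nucleus_mask`, `abundance_maps`, `target_fraction`,
#'   `true_fraction`).
#' @export
render_lambda_stack <- function(spec, grid = wavelength_grid(),
                                meta = acquisition_meta()) {
  stopifnot(inherits(spec, "phantom_spec"))
  cs <- default_components()
  truth <- phantom_truth(spec, cs)
  labels <- channel_labels(grid)
  basis <- vapply(labels, function(lam) {
    exp(-(lam - cs$center_nm)^2 / (2 * cs$sigma_init_nm^2))
  }, numeric(nrow(cs))) # components x channels
  flat <- do.call(cbind, lapply(truth$abundance_maps, as.vector))
  px <- flat %*% basis # pixels x channels
  arr <- array(px, dim = c(spec$height, spec$width, grid$n_channels))
  arr <- withr::with_seed(
    spec$seed + 2L,
    apply_detection_noise(arr, spec$poisson_scale, spec$gaussian_sd)
  )
  list(stack = lambda_stack(arr, grid, meta), truth = truth)
}

#' Render a phantom as a two-channel TPEF/SHG image
#'
#' Integrates the matched noiseless lambda stack over the SHG and TPEF
#' detector bands, then applies the detection noise after integration. For
#' the same seed it shares its ground truth with [render_lambda_stack()],
#' and with noise disabled the two routes agree exactly.
#'
#' @param spec A [phantom_spec()].
#' @param grid,meta Acquisition geometry.
#' @return A list: `image` (a [two_channel_image()]) and `truth` (as in
#'   [render_lambda_stack()]).
#' @export
render_two_channel <- function(spec, grid = wavelength_grid(),
                               meta = acquisition_meta()) {
  noiseless_spec <- spec
  noiseless_spec$poisson_scale <- 0
  noiseless_spec$gaussian_sd <- 0
  rendered <- render_lambda_stack(noiseless_spec, grid, meta)
  shg <- band_integrate(rendered$stack, meta$shg_band)
  tpef <- band_integrate(rendered$stack, meta$tpef_band)
  noisy <- withr::with_seed(spec$seed + 2L, {
    list(shg = apply_detection_noise(shg, spec$poisson_scale,
                                     spec$gaussian_sd),
         tpef = apply_detection_noise(tpef, spec$poisson_scale,
                                      spec$gaussian_sd))
  })
  list(image = two_channel_image(noisy$shg, noisy$tpef, meta),
       truth = rendered$truth)
}

#' Noiseless reference spectrum from a component mixing vector
#'
#' Evaluates the sum of the default component bases with the given
#' amplitudes on a fine 1-nm grid over 382--714 nm -- the standard input for
#' fit round-trip checks and for synthesizing the published tissue mixture
#' (see [fibrous_meningioma_ratios()]).
#'
#' @param amplitudes Eight non-negative amplitudes in component (center)
#'   order.
#' @param components A component set; see [default_components()].
#' @param step_nm Wavelength sampling step (default 1 nm).
#' @return An [emission_spectrum()] (not normalized).
#' @export
reference_spectrum <- function(amplitudes, components = default_components(),
                               step_nm = 1) {
  cs <- validate_component_set(components)
  stopifnot(length(amplitudes) == nrow(cs), all(amplitudes >= 0))
  w <- seq(382, 714, by = step_nm)
  emission_spectrum(w, component_model(amplitudes, cs$center_nm,
                                       cs$sigma_init_nm, w))
}
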