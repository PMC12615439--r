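make_stack <- function(px, grid = wavelength_grid(), meta = acquisition_meta()) {
  lambda_stack(px, grid, meta)
}

test_that("roi_mean_spectrum averages per channel", {
  g <- wavelength_grid(400, 10, 2)
  m <- acquisition_meta(shg_band = c(395, 405), tpef_band = c(406, 500))
  px <- array(0, dim = c(2, 1, 2))
  px[1, 1, ] <- c(1, 3)
  px[2, 1, ] <- c(3, 5)
  s <- roi_mean_spectrum(make_stack(px, g, m))
  expect_equal(s$intensity, c(2, 4))
  expect_false(is_normalized(s))

  # constant stack -> flat spectrum
  const <- make_stack(array(7, dim = c(4, 5, 32)))
  expect_equal(roi_mean_spectrum(const)$intensity, rep(7, 32))

  # single-pixel ROI returns that pixel's spectrum exactly
  set.seed(42)
  px <- array(runif(4 * 4 * 32), dim = c(4, 4, 32))
  stk <- make_stack(px)
  roi <- matrix(FALSE, 4, 4)
  roi[2, 3] <- TRUE
  expect_equal(roi_mean_spectrum(stk, roi)$intensity, px[2, 3, ])

  expect_error(roi_mean_spectrum(stk, matrix(FALSE, 4, 4)), "empty")
  expect_error(roi_mean_spectrum(stk, c(1, 9, 1, 2)), "out of range")
})

test_that("normalize_spectrum scales to unit peak, idempotently", {
  s <- emission_spectrum(c(400, 500, 600), c(2, 4, 8))
  n <- normalize_spectrum(s)
  expect_equal(n$intensity, c(0.25, 0.5, 1))
  expect_true(is_normalized(n))
  expect_equal(normalize_spectrum(n)$intensity, n$intensity)

  # scale invariance: normalize(c * s) == normalize(s) for any c > 0
  for (c_ in c(1e-3, 0.7, 42)) {
    scaled <- emission_spectrum(s$wavelength_nm, c_ * s$intensity)
    expect_equal(normalize_spectrum(scaled)$intensity, n$intensity)
  }

  zero <- emission_spectrum(c(1, 2), c(0, 0))
  expect_error(normalize_spectrum(zero), "all-zero")
})

test_that("band_integrate sums exactly the channels inside the band", {
  set.seed(7)
  px <- array(runif(6 * 6 * 32), dim = c(6, 6, 32))
  stk <- make_stack(px)
  labs <- channel_labels(stk$grid)

  shg <- band_integrate(stk, c(389, 419))
  expect_equal(sort(labs[labs >= 389 & labs <= 419]), c(393, 404, 415))
  expect_equal(shg, px[, , 2] + px[, , 3] + px[, , 4])

  full <- band_integrate(stk, range(labs))
  expect_equal(full, rowSums(px, dims = 2))

  expect_error(band_integrate(stk, c(1000, 1100)), "no grid channels")

  # conservation: disjoint bands tiling the grid sum to the full integral
  parts <- band_integrate(stk, c(382, 450)) +
    band_integrate(stk, c(451, 600)) +
    band_integrate(stk, c(601, 723))
  expect_equal(parts, full)
})

test_that("combined spectral render maps SHG to purple, TPEF to blue", {
  px <- array(0, dim = c(3, 3, 32))
  px[1, 1, 3] <- 5 # 404 nm: inside the SHG band
  rgb <- combine_spectral_image(make_stack(px))
  expect_equal(rgb[1, 1, ], c(1, 0, 1)) # pure purple
  expect_equal(max(rgb[, , 2]), 0)

  px2 <- array(0, dim = c(3, 3, 32))
  px2[2, 2, 15] <- 2 # 536 nm: TPEF band
  rgb2 <- combine_spectral_image(make_stack(px2))
  expect_equal(rgb2[2, 2, ], c(0, 0, 1)) # pure blue

  black <- combine_spectral_image(make_stack(array(0, dim = c(3, 3, 32))))
  expect_equal(max(black), 0)

  # invariance under global intensity scaling
  expect_equal(combine_spectral_image(make_stack(px * 1000)), rgb)
})

test_that("TPEF/SHG overlay uses green SHG, red TPEF, yellow where both", {
  shg <- matrix(0, 2, 2); tpef <- matrix(0, 2, 2)
  shg[1, 1] <- 3            # SHG only -> green
  tpef[1, 2] <- 2           # TPEF only -> red
  shg[2, 2] <- 3; tpef[2, 2] <- 2 # both at channel max -> yellow
  rgb <- overlay_tpef_shg(two_channel_image(shg, tpef))
  expect_equal(rgb[1, 1, ], c(0, 1, 0))
  expect_equal(rgb[1, 2, ], c(1, 0, 0))
  expect_equal(rgb[2, 2, ], c(1, 1, 0))
  expect_equal(max(rgb[, , 3]), 0)

  zero <- overlay_tpef_shg(two_channel_image(matrix(0, 2, 2), matrix(0, 2, 2)))
  expect_equal(max(zero), 0)
  expect_equal(overlay_tpef_shg(two_channel_image(shg * 9, tpef * 9)), rgb)
})

test_that("TIFF round trips preserve pixels and reject page mismatches", {
  dir <- withr::local_tempdir()
  set.seed(99)

  # 16-bit integer lambda stack: bit-exact round trip
  px <- array(as.numeric(sample(0:65535, 4 * 5 * 32, replace = TRUE)),
              dim = c(4, 5, 32))
  stk <- make_stack(px)
  p <- file.path(dir, "stack.tif")
  write_stack(stk, p)
  back <- read_stack(p)
  expect_s3_class(back, "lambda_stack")
  expect_identical(back$pixels, px)
  expect_equal(channel_labels(back$grid), channel_labels(stk$grid))
  expect_equal(back$meta$shg_band, stk$meta$shg_band)

  # float two-channel image: exact to float32 precision
  img <- two_channel_image(matrix(runif(12, 0, 7), 3, 4),
                           matrix(runif(12, 0, 7), 3, 4))
  p2 <- file.path(dir, "tc.tif")
  write_stack(img, p2)
  back2 <- read_stack(p2)
  expect_s3_class(back2, "two_channel_image")
  expect_no_diff(back2$shg, img$shg, 1e-5)
  expect_no_diff(back2$tpef, img$tpef, 1e-5)

  # declared 32 channels but a 2-page file: format error
  sidecar <- jsonlite::read_json(file.path(dir, "tc.json"),
                                 simplifyVector = TRUE)
  sidecar$kind <- "lambda_stack"
  sidecar$n_channels <- 32
  sidecar$start_nm <- 382; sidecar$step_nm <- 11
  jsonlite::write_json(sidecar, file.path(dir, "tc.json"), auto_unbox = TRUE)
  expect_error(read_stack(p2), "format error")
})

test_that("spectrum CSV round trip is exact", {
  dir <- withr::local_tempdir()
  set.seed(3)
  s <- emission_spectrum(seq(382, 714, by = 11), runif(31, 0, 2))
  p <- file.path(dir, "spec.csv")
  write_spectrum_csv(s, p)
  back <- read_spectrum_csv(p)
  expect_equal(back$wavelength_nm, s$wavelength_nm, tolerance = 1e-12)
  expect_equal(back$intensity, s$intensity, tolerance = 1e-12)
  expect_error(read_spectrum_csv(file.path(dir, "missing.csv")), "not found")
})
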