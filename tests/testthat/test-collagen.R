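test_that("enhance stretches between the requested percentiles", {
  set.seed(5)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  e <- enhance(img, segmentation_params(1, 99))
  expect_true(all(e >= 0 & e <= 1))
  expect_lt(e[which.min(img)], 0.02)
  expect_equal(e[which.max(img)], 1)

  # a ramp already in [0,1] with (0, 100) percentiles is the identity
  ramp <- matrix(seq(0, 1, length.out = 100), 10, 10)
  expect_no_diff(enhance(ramp, segmentation_params(0, 100)), ramp, 1e-12)

  expect_equal(enhance(matrix(3, 5, 5)), matrix(0, 5, 5))
})

test_that("otsu_threshold separates a perfect bimodal image", {
  img <- matrix(rep(c(0.1, 0.9), each = 50), 10, 10)
  t <- otsu_threshold(img)
  expect_gt(t, 0.1)
  expect_lte(t, 0.9)
  expect_equal(sum(img >= t), 50)
  expect_error(otsu_threshold(matrix(0.5, 4, 4)), "degenerate")
  expect_error(otsu_threshold(matrix(c(0.5, 3), 2, 1)), "\\[0, 1\\]")
})

test_that("otsu_threshold equals the exhaustive bin-edge maximizer", {
  toy <- matrix(c(1, 1, 1, 1, 2, 2, 2, 2, 8, 8, 9, 9, 9, 9, 10, 10) / 10,
                4, 4)
  expect_equal(otsu_threshold(toy, 256), brute_force_otsu(toy, 256))

  set.seed(314)
  for (k in 1:12) {
    img <- matrix(runif(256)^runif(1, 0.5, 2), 16, 16)
    expect_equal(otsu_threshold(img, 256), brute_force_otsu(img, 256))
    expect_equal(otsu_threshold(img, 64), brute_force_otsu(img, 64))
  }
})

test_that("otsu classification matches raw-pixel and EBImage references", {
  ph <- render_two_channel(small_phantom_spec(seed = 8))
  e <- enhance(ph$image$shg, segmentation_params())
  t_pkg <- otsu_threshold(e)

  t_raw <- raw_pixel_otsu(e)
  agree_raw <- mean((e >= t_pkg) == (e >= t_raw))
  expect_gte(agree_raw, 0.95)

  t_eb <- EBImage::otsu(e, range = c(0, 1), levels = 256)
  agree_eb <- mean((e >= t_pkg) == (e > t_eb))
  expect_gte(agree_eb, 0.99)
})

test_that("morphological cleanup removes speckle and fills holes", {
  p <- segmentation_params()
  speck <- matrix(FALSE, 10, 10)
  speck[5, 5] <- TRUE
  expect_false(any(morph_clean(speck, p)))

  solid <- matrix(FALSE, 30, 30)
  solid[5:24, 5:24] <- TRUE
  holed <- solid
  holed[12, 12] <- FALSE
  expect_equal(morph_clean(holed, p), solid)

  expect_identical(morph_clean(holed, segmentation_params(selem_radius = 0)),
                   holed)
})

test_that("collagen_content counts the pixel fraction exactly", {
  m <- matrix(FALSE, 10, 10)
  m[sample(100, 37)] <- TRUE
  expect_equal(collagen_content(m), 0.37)
  expect_equal(collagen_content(matrix(FALSE, 3, 3)), 0)
  expect_equal(collagen_content(matrix(TRUE, 3, 3)), 1)
})

test_that("dice_coefficient scores mask overlap", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  b <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, b), 0.5)
  expect_equal(dice_coefficient(a & FALSE, b & FALSE), 1)
})

test_that("quantify_shg runs the fixed stage order and keeps intermediates", {
  ph <- render_two_channel(small_phantom_spec(seed = 2))
  p <- segmentation_params()
  seg <- quantify_shg(ph$image, p)

  expect_equal(seg$stages$enhanced, enhance(ph$image$shg, p))
  expect_equal(seg$threshold, otsu_threshold(seg$stages$enhanced, p$hist_bins))
  expect_equal(seg$stages$binary, seg$stages$enhanced >= seg$threshold)
  expect_equal(seg$mask, morph_clean(seg$stages$binary, p))
  expect_equal(seg$collagen_content, collagen_content(seg$mask))
  expect_gt(seg$threshold, 0)
  expect_lt(seg$threshold, 1)
})

test_that("an already-binary morphologically regular image is reproduced", {
  img <- matrix(0, 40, 40)
  img[5:20, 5:30] <- 1   # 16 x 26 block
  img[30:38, 10:35] <- 1 # 9 x 26 block
  seg <- quantify_shg(img)
  expect_equal(seg$collagen_content, mean(img == 1))
  expect_equal(seg$mask, img == 1)
})

test_that("degenerate images propagate the Otsu error", {
  expect_error(quantify_shg(matrix(0, 16, 16)), "degenerate")
})

test_that("content recovery and cross-modality agreement hold on phantoms", {
  spec <- small_phantom_spec(seed = 21, target = 0.45)
  tc <- render_two_channel(spec)
  seg <- quantify_shg(tc$image)
  expect_lt(abs(seg$collagen_content - tc$truth$true_fraction), 0.05)
  expect_gte(dice_coefficient(seg$mask, tc$truth$collagen_mask), 0.8)

  st <- render_lambda_stack(spec)
  segc <- quantify_combined(st$stack)
  expect_lt(abs(segc$collagen_content - st$truth$true_fraction), 0.05)
  expect_lt(abs(segc$collagen_content - seg$collagen_content), 0.05)

  # noiseless phantom at the generator's default field size: near-perfect
  clean <- render_lambda_stack(phantom_spec(seed = 21,
                                            target_collagen_fraction = 0.45,
                                            poisson_scale = 0,
                                            gaussian_sd = 0))
  seg0 <- quantify_combined(clean$stack)
  # thresholding alone recovers the truth mask; the morphological cleanup
  # then (by design) removes fibers thinner than the structuring element,
  # costing a few points of Dice
  expect_gte(dice_coefficient(seg0$stages$binary, clean$truth$collagen_mask),
             0.99)
  expect_gte(dice_coefficient(seg0$mask, clean$truth$collagen_mask), 0.9)
})

test_that("an empty SHG band raises a band error", {
  px <- array(1, dim = c(4, 4, 3))
  g <- wavelength_grid(500, 10, 3)
  m <- acquisition_meta(shg_band = c(389, 419), tpef_band = c(430, 716))
  expect_error(quantify_combined(lambda_stack(px, g, m)), "no grid channels")
})

test_that("content is invariant under monotone pre-transforms", {
  ph <- render_two_channel(small_phantom_spec(seed = 17))
  p <- segmentation_params(enhance_low_pct = 0, enhance_high_pct = 100)
  base <- quantify_shg(ph$image$shg, p)$collagen_content
  for (f in list(sqrt, function(x) x^2, function(x) log1p(3 * x))) {
    trans <- quantify_shg(f(ph$image$shg), p)$collagen_content
    expect_lt(abs(trans - base), 0.02)
  }
})

test_that("adding collagen never decreases the estimated content", {
  contents <- vapply(c(0.2, 0.35, 0.5, 0.65), function(tf) {
    ph <- render_two_channel(small_phantom_spec(seed = 5, target = tf))
    quantify_shg(ph$image)$collagen_content
  }, numeric(1))
  expect_true(all(diff(contents) > 0))
})

test_that("batch_report computes per-modality mean and sample SD", {
  masks <- lapply(c(0.4, 0.5, 0.6), function(f) {
    img <- matrix(0, 40, 40)
    img[seq_len(1600 * f)] <- 1
    img
  })
  # block images are binary; the pipeline reproduces their fraction exactly
  batch <- batch_report(setNames(masks, c("a", "b", "c")))
  expect_equal(batch$per_image$collagen_content, c(0.4, 0.5, 0.6))
  expect_equal(batch$summary$mean_content, 0.5)
  expect_equal(batch$summary$sd_content, 0.1)
  expect_equal(batch$summary$n, 3L)

  single <- batch_report(list(only = masks[[2]]))
  expect_equal(single$summary$mean_content, 0.5)
  expect_true(is.na(single$summary$sd_content))
})

test_that("a cohort-scale phantom batch recovers the cohort mean", {
  set.seed(77)
  fracs <- pmin(pmax(rnorm(14, 0.53, 0.13), 0.1), 0.9)
  inputs <- lapply(seq_along(fracs), function(i) {
    render_two_channel(small_phantom_spec(seed = 100 + i,
                                          target = fracs[i]))$image
  })
  batch <- batch_report(inputs)
  expect_equal(nrow(batch$per_image), 14)
  expect_lt(abs(batch$summary$mean_content - 0.53), 0.08)
  expect_gt(batch$summary$sd_content, 0)
})
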