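#' Parameters of the collagen segmentation pipeline
#'
#' Controls the four fixed stages of collagen quantification:
#' percentile-based contrast enhancement, Otsu thresholding on a histogram
#' with `hist_bins` bins, and morphological opening-then-closing with a
#' structuring element of radius `selem_radius`.
#'
#' @param enhance_low_pct,enhance_high_pct Percentiles mapped to 0 and 1 by
#'   the contrast stretch; `0 <= low < high <= 100`.
#' @param hist_bins Otsu histogram resolution (>= 2); 256 matches the
#'   classical 8-bit formulation.
#' @param selem_radius Structuring-element radius in pixels (0 disables the
#'   morphological cleanup).
#' @param selem_shape `"disk"` or `"square"`.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(enhance_low_pct = 1, enhance_high_pct = 99,
                                hist_bins = 256L, selem_radius = 1L,
                                selem_shape = c("disk", "square")) {
  selem_shape <- match.arg(selem_shape)
  stopifnot(enhance_low_pct >= 0, enhance_high_pct <= 100,
            enhance_low_pct < enhance_high_pct,
            hist_bins >= 2, selem_radius >= 0)
  structure(list(enhance_low_pct = enhance_low_pct,
                 enhance_high_pct = enhance_high_pct,
                 hist_bins = as.integer(hist_bins),
                 selem_radius = as.integer(selem_radius),
                 selem_shape = selem_shape),
            class = "segmentation_params")
}

#' Percentile contrast stretch
#'
#' Linear rescale mapping the low percentile of the intensity distribution
#' to 0 and the high percentile to 1, clipping outside; this highlights
#' collagen fibers against the background before thresholding. A constant
#' image maps to all zeros.
#'
#' @param img Numeric matrix.
#' @param params A [segmentation_params()].
#' @return Matrix with values in `[0, 1]`.
#' @export
enhance <- function(img, params = segmentation_params()) {
  stopifnot(is.matrix(img), length(img) >= 1)
  q <- quantile(img, c(params$enhance_low_pct, params$enhance_high_pct) / 100,
                names = FALSE)
  if (q[2] <= q[1]) {
    return(matrix(0, nrow(img), ncol(img)))
  }
  pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Otsu's threshold from the image histogram
#'
#' Computes the classical Otsu threshold of an image with values in
#' `[0, 1]`: the histogram with `bins` equal bins is split at each interior
#' bin edge, and the edge maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` (class means taken at bin midpoints) is
#' returned. Exact ties resolve to the lowest qualifying edge. Pixels with
#' value `>= threshold` are foreground.
#'
#' @param img Numeric matrix (or vector) with values in `[0, 1]` and at
#'   least two distinct values.
#' @param bins Histogram resolution (default 256).
#' @return The threshold, a bin edge in `(0, 1)`.
#' @export
otsu_threshold <- function(img, bins = 256L) {
  v <- as.numeric(img)
  stopifnot(length(v) >= 2, bins >= 2)
  if (min(v) < -1e-12 || max(v) > 1 + 1e-12) {
    stop("otsu_threshold() expects intensities in [0, 1]; enhance() first",
         call. = FALSE)
  }
  if (max(v) - min(v) <= 0) {
    stop("degenerate input: constant image has no Otsu threshold",
         call. = FALSE)
  }
  bins <- as.integer(bins)
  idx <- pmin(pmax(floor(v * bins) + 1L, 1L), bins)
  p <- tabulate(idx, bins) / length(v)
  mids <- (seq_len(bins) - 0.5) / bins
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mu_total <- m0[bins]
  i <- seq_len(bins - 1L)
  w1 <- 1 - w0[i]
  valid <- w0[i] > 0 & w1 > 0
  bcv <- rep(-Inf, bins - 1L)
  bcv[valid] <- w0[i][valid] * w1[valid] *
    (m0[i][valid] / w0[i][valid] - (mu_total - m0[i][valid]) / w1[valid])^2
  best <- which.max(bcv) # first maximum = lowest qualifying edge
  best / bins
}

#' Morphological cleanup of a binary mask
#'
#' Binary opening (erosion then dilation, removing speckle smaller than the
#' structuring element) followed by closing (dilation then erosion, filling
#' holes and gaps), in that order. Radius 0 is the identity.
#'
#' @param mask Logical matrix.
#' @param params A [segmentation_params()].
#' @return Logical matrix of the same shape.
#' @export
morph_clean <- function(mask, params = segmentation_params()) {
  stopifnot(is.logical(mask), is.matrix(mask))
  r <- params$selem_radius
  if (r == 0) return(mask)
  brush <- EBImage::makeBrush(2L * r + 1L,
                              shape = if (params$selem_shape == "disk")
                                "disc" else "box")
  m <- EBImage::closing(EBImage::opening(mask * 1, brush), brush)
  matrix(as.numeric(m) > 0.5, nrow(mask), ncol(mask))
}

#' Collagen content of a segmentation mask
#'
#' The pixel fraction classified as collagen: true pixels divided by total
#' pixels, exactly.
#'
#' @param mask Logical matrix.
#' @return Fraction in `[0, 1]`.
#' @export
collagen_content <- function(mask) {
  stopifnot(is.logical(mask), length(mask) >= 1)
  sum(mask) / length(mask)
}

#' Dice overlap between two masks
#'
#' `2|A & B| / (|A| + |B|)`; two empty masks score 1.
#'
#' @param a,b Logical matrices of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(is.logical(a), is.logical(b), identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Quantify collagen content in an SHG image
#'
#' Runs the fixed four-stage pipeline on the SHG channel: percentile
#' enhancement, Otsu thresholding, morphological opening/closing, then the
#' pixel-fraction collagen content. All stage images are retained so each
#' intermediate can be inspected or plotted.
#'
#' @param x A [two_channel_image()] (its SHG channel is used) or a plain
#'   non-negative intensity matrix.
#' @param params A [segmentation_params()].
#' @return An object of class `collagen_segmentation`: `mask`, `threshold`
#'   (on the enhanced `[0,1]` scale), `collagen_content`, `modality`,
#'   `stages` (list of `input`, `enhanced`, `binary`, `cleaned`), `params`.
#' @export
quantify_shg <- function(x, params = segmentation_params()) {
  img <- if (inherits(x, "two_channel_image")) x$shg else x
  stopifnot(is.matrix(img))
  run_segmentation(img, params, modality = "shg")
}

#' Quantify collagen content in a 32-channel combined spectral image
#'
#' Reduces the lambda stack to a collagen-weighted grayscale by integrating
#' the SHG detector band ([band_integrate()] over `meta$shg_band`), then
#' applies the same pipeline as [quantify_shg()].
#'
#' @param stack A [lambda_stack()].
#' @param params A [segmentation_params()].
#' @return A `collagen_segmentation`; see [quantify_shg()].
#' @export
quantify_combined <- function(stack, params = segmentation_params()) {
  stopifnot(inherits(stack, "lambda_stack"))
  gray <- band_integrate(stack, stack$meta$shg_band)
  run_segmentation(gray, params, modality = "combined")
}

#' @keywords internal
run_segmentation <- function(img, params, modality) {
  stopifnot(inherits(params, "segmentation_params"))
  enhanced <- enhance(img, params)
  thr <- otsu_threshold(enhanced, params$hist_bins)
  binary <- enhanced >= thr
  cleaned <- morph_clean(binary, params)
  structure(
    list(mask = cleaned, threshold = thr,
         collagen_content = collagen_content(cleaned),
         modality = modality,
         stages = list(input = img, enhanced = enhanced, binary = binary,
                       cleaned = cleaned),
         params = params),
    class = "collagen_segmentation"
  )
}

#' @export
print.collagen_segmentation <- function(x, ...) {
  cat(sprintf(
    "<collagen_segmentation> modality %s | threshold %.4f | collagen content %.4f\n",
    x$modality, x$threshold, x$collagen_content))
  invisible(x)
}

#' @method glance collagen_segmentation
#' @export
glance.collagen_segmentation <- function(x, ...) {
  tibble(modality = x$modality, threshold = x$threshold,
         collagen_content = x$collagen_content,
         n_pixels = length(x$mask))
}

#' Plot the four pipeline stages of a segmentation
#'
#' Facets the original image, the enhanced image, the raw Otsu mask and the
#' cleaned mask, mirroring the panels used to present the collagen pipeline.
#'
#' @param x A `collagen_segmentation`.
#' @return A ggplot object.
#' @export
plot_segmentation_stages <- function(x) {
  stopifnot(inherits(x, "collagen_segmentation"))
  stage_df <- function(m, label) {
    g <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
    g$value <- as.numeric(m) / max(as.numeric(m), 1e-12)
    g$stage <- label
    g
  }
  df <- rbind(stage_df(x$stages$input, "1: original"),
              stage_df(x$stages$enhanced, "2: enhanced"),
              stage_df(x$stages$binary * 1, "3: thresholded"),
              stage_df(x$stages$cleaned * 1, "4: cleaned"))
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    facet_wrap(~stage) +
    scale_y_reverse() +
    scale_fill_gradient(low = "black", high = "white", guide = "none") +
    coord_fixed() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Batch collagen quantification with per-modality summary
#'
#' Applies the collagen pipeline to a collection of inputs and reports one
#' row per image plus a per-modality mean and sample standard deviation
#' (n - 1 denominator; a single image reports `NA` SD), the convention used
#' for cohort-level collagen content.
#'
#' @param inputs A list of inputs -- [two_channel_image()] / intensity
#'   matrices (analysed as modality `"shg"`) and/or [lambda_stack()]s
#'   (modality `"combined"`) -- or a character vector of TIFF paths read via
#'   [read_stack()]. List names populate the `file` column.
#' @param params A [segmentation_params()].
#' @return An object of class `collagen_batch`: a list with `per_image`
#'   (tibble `file`, `modality`, `threshold`, `collagen_content`) and
#'   `summary` (tibble `modality`, `n`, `mean_content`, `sd_content`).
#' @export
batch_report <- function(inputs, params = segmentation_params()) {
  if (is.character(inputs)) {
    paths <- inputs
    inputs <- lapply(paths, read_stack)
    names(inputs) <- paths
  }
  stopifnot(is.list(inputs), length(inputs) >= 1)
  if (is.null(names(inputs))) {
    names(inputs) <- sprintf("input_%02d", seq_along(inputs))
  }
  rows <- lapply(names(inputs), function(nm) {
    obj <- inputs[[nm]]
    seg <- if (inherits(obj, "lambda_stack")) {
      quantify_combined(obj, params)
    } else {
      quantify_shg(obj, params)
    }
    tibble(file = nm, modality = seg$modality, threshold = seg$threshold,
           collagen_content = seg$collagen_content)
  })
  per_image <- dplyr::bind_rows(rows)
  summary <- per_image |>
    dplyr::group_by(.data$modality) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_content = mean(.data$collagen_content),
                     sd_content = sd(.data$collagen_content),
                     .groups = "drop")
  structure(list(per_image = per_image, summary = summary),
            class = "collagen_batch")
}

#' @export
print.collagen_batch <- function(x, ...) {
  cat("<collagen_batch>\n")
  print(x$per_image)
  cat("per-modality mean +/- SD:\n")
  print(x$summary)
  invisible(x)
}
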