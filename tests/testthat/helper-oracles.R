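# Independent oracles and small fixtures used across the suite.

# Exhaustive Otsu oracle over histogram bin edges, computed by a naive
# O(bins^2) double loop from the binned histogram (independent of the
# package's vectorised cumulative-sum implementation).
brute_force_otsu <- function(v, bins = 256L) {
  v <- as.numeric(v)
  idx <- pmin(pmax(floor(v * bins) + 1L, 1L), bins)
  counts <- tabulate(idx, bins)
  mids <- (seq_len(bins) - 0.5) / bins
  n <- length(v)
  best_i <- NA_integer_
  best_bcv <- -Inf
  for (i in seq_len(bins - 1L)) {
    n0 <- sum(counts[1:i])
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:i] * mids[1:i]) / n0
    mu1 <- sum(counts[(i + 1):bins] * mids[(i + 1):bins]) / n1
    bcv <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (bcv > best_bcv) { # strict: ties keep the lowest edge
      best_bcv <- bcv
      best_i <- i
    }
  }
  best_i / bins
}

# Between-class variance maximiser computed from the raw pixel values (no
# histogram): scans the same candidate edges but takes exact class means.
raw_pixel_otsu <- function(v, bins = 256L) {
  v <- as.numeric(v)
  best_t <- NA_real_
  best_bcv <- -Inf
  for (i in seq_len(bins - 1L)) {
    t <- i / bins
    lo <- v < t
    if (!any(lo) || all(lo)) next
    w0 <- mean(lo)
    bcv <- w0 * (1 - w0) * (mean(v[lo]) - mean(v[!lo]))^2
    if (bcv > best_bcv) {
      best_bcv <- bcv
      best_t <- t
    }
  }
  best_t
}

# small, fast phantom used by unit tests (acceptance uses full 256 x 256)
small_phantom_spec <- function(seed = 1L, target = 0.4, n_cells = 10, ...) {
  phantom_spec(height = 128, width = 128, n_cells = n_cells,
               target_collagen_fraction = target, seed = seed, ...)
}

expect_no_diff <- function(a, b, tol) {
  expect_lt(max(abs(a - b)), tol)
}
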