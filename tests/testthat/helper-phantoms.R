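# Shared fixture builders: small, fast phantom configurations.

# Flat rectangular noiseless sample; optionally overridden per test.
flat_config <- function(group = "CONT", ...) {
  phantom_config(group = group, noise_model = "none",
                 undulation_amplitude_px = 0, ...)
}

# Build a quantized_map from explicit integer levels by routing values through
# quantize() with a unit-width binning (value v in [0, L) maps to level
# floor(v)), so tests can state level patterns directly.
qmap_from_levels <- function(levels_mat, L) {
  vals <- levels_mat + 0.5
  roi <- !is.na(levels_mat)
  vals[!roi] <- NA_real_
  quantize(vals, roi, levels = L, range_mode = "fixed", range_ms = c(0, L))
}

# Independent brute-force GLCM oracle: double loop over all pixels, counting
# ordered pairs in both directions, then normalizing.
brute_glcm <- function(levels_mat, L, drow, dcol) {
  counts <- matrix(0, L, L)
  nr <- nrow(levels_mat); nc <- ncol(levels_mat)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      r2 <- r + drow; c2 <- cc + dcol
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      a <- levels_mat[r, cc]; b <- levels_mat[r2, c2]
      if (is.na(a) || is.na(b)) next
      counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
      counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1
    }
  }
  counts / sum(counts)
}

# Independent brute-force feature oracle: plain double sums over the matrix.
brute_features <- function(p) {
  L <- nrow(p)
  contrast <- homog <- energy <- mu <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    contrast <- contrast + p[i + 1, j + 1] * (i - j)^2
    homog <- homog + p[i + 1, j + 1] / (1 + abs(i - j))
    energy <- energy + p[i + 1, j + 1]^2
    mu <- mu + i * p[i + 1, j + 1]
  }
  variance <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1))
    variance <- variance + p[i + 1, j + 1] * (i - mu)^2
  c(contrast = contrast, homogeneity = homog, energy = energy,
    variance = variance)
}

# Random undulating mask with per-column contiguous runs of varying height.
random_undulating_mask <- function(nr = 20, nc = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(FALSE, nr, nc)
  for (cc in seq_len(nc)) {
    top <- sample(2:5, 1)
    h <- sample(5:(nr - top), 1)
    mask[top:(top + h - 1), cc] <- TRUE
  }
  mask
}

# Long measurement table from explicit per-sample time courses.
toy_long_table <- function(values, groups, time_points = paste0("t", 0:3),
                           roi = "whole", measure = "t2_mean") {
  # values: matrix samples x time points
  n <- nrow(values)
  data.frame(
    sample_id = rep(sprintf("s%02d", seq_len(n)), times = ncol(values)),
    group = rep(groups, times = ncol(values)),
    time_point = rep(time_points, each = n),
    roi = roi, measure = measure,
    value = as.vector(values), stringsAsFactors = FALSE)
}
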