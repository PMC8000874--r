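test_that("quantization bins uniformly with clipping and bin centres", {
  m <- matrix(41.9, 1, 1)
  q <- quantize(m, matrix(TRUE, 1, 1), levels = 32, range_ms = c(0, 120))
  expect_equal(q$levels_img[1, 1], floor(41.9 / 120 * 32))  # level 11
  # clipping at the range ends
  m2 <- matrix(c(-5, 200, 0, 120), 2, 2)
  q2 <- quantize(m2, matrix(TRUE, 2, 2), levels = 32, range_ms = c(0, 120))
  expect_equal(q2$levels_img[1, 1], 0L)
  expect_equal(q2$levels_img[2, 1], 31L)
  expect_equal(q2$levels_img[2, 2], 31L)   # top edge maps into the last bin
  # back-mapping through bin centres stays within half a bin width
  set.seed(12)
  m3 <- matrix(runif(100, 0, 120), 10, 10)
  q3 <- quantize(m3, matrix(TRUE, 10, 10), levels = 32, range_ms = c(0, 120))
  err <- abs(q3$bin_centers[q3$levels_img + 1L] - m3)
  expect_true(all(err <= 120 / 32 / 2 + 1e-12))
})

test_that("constant maps collapse to a single level under roi_minmax", {
  m <- matrix(55, 4, 4)
  q <- quantize(m, matrix(TRUE, 4, 4), levels = 16, range_mode = "roi_minmax")
  expect_true(all(q$levels_img == 0L))
  expect_error(quantize(m, matrix(TRUE, 4, 4), levels = 1), "levels")
  expect_error(quantize(m, matrix(FALSE, 4, 4)), "usable")
})

test_that("a single horizontal pair yields the symmetric two-entry GLCM", {
  lv <- matrix(c(3L, 7L), 1, 2)
  q <- qmap_from_levels(lv, L = 8)
  g <- glcm(q, 0)
  expect_equal(g$matrix[4, 8], 0.5)
  expect_equal(g$matrix[8, 4], 0.5)
  expect_equal(sum(g$matrix), 1)
  expect_equal(g$n_pairs, 1)
})

test_that("checkerboard GLCMs and features match the closed form", {
  lv <- matrix(as.integer((outer(1:4, 1:4, "+")) %% 2), 4, 4)
  q <- qmap_from_levels(lv, L = 2)
  g0 <- glcm(q, 0)
  expect_equal(g0$n_pairs, 12)           # 12 horizontal pairs in a 4x4 grid
  expect_equal(g0$matrix, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  f0 <- glcm_features(g0)
  expect_equal(f0$contrast, 1)
  expect_equal(f0$homogeneity, 0.5)
  expect_equal(f0$energy, 0.5)
  expect_equal(f0$variance, 0.25)
  # diagonal neighbours of a checkerboard are equal-valued
  f45 <- glcm_features(glcm(q, 45))
  expect_equal(f45$contrast, 0)
  expect_equal(f45$homogeneity, 1)
  avg <- orientation_averaged_features(q, ms_variance = FALSE)
  expect_equal(avg$averaged$contrast, 0.5)
  expect_setequal(avg$orientations_used, c(0, 45, 90, 135))
})

test_that("GLCMs and features match the brute-force oracle on random images", {
  offsets <- list("0" = c(0L, 1L), "45" = c(-1L, 1L),
                  "90" = c(-1L, 0L), "135" = c(-1L, -1L))
  set.seed(19)
  for (rep in 1:20) {
    L <- sample(3:8, 1)
    lv <- matrix(sample(0:(L - 1), 64, replace = TRUE), 8, 8)
    lv[sample(64, 10)] <- NA              # undefined pixels must be skipped
    q <- qmap_from_levels(lv, L = L)
    for (o in names(offsets)) {
      g <- glcm(q, as.numeric(o))
      oracle <- brute_glcm(lv, L, offsets[[o]][1], offsets[[o]][2])
      expect_equal(g$matrix, oracle, tolerance = 1e-12)
      f <- glcm_features(g)
      bf <- brute_features(g$matrix)
      expect_equal(unlist(f), bf, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("uniform regions give the degenerate feature values", {
  q <- qmap_from_levels(matrix(5L, 6, 6), L = 8)
  avg <- orientation_averaged_features(q, ms_variance = FALSE)$averaged
  expect_equal(avg$contrast, 0)
  expect_equal(avg$homogeneity, 1)
  expect_equal(avg$energy, 1)
  expect_equal(avg$variance, 0)
})

test_that("feature ranges hold and reflection of levels leaves them unchanged", {
  set.seed(23)
  for (rep in 1:10) {
    L <- 6
    lv <- matrix(sample(0:(L - 1), 49, replace = TRUE), 7, 7)
    q <- qmap_from_levels(lv, L = L)
    f <- orientation_averaged_features(q, ms_variance = FALSE)$averaged
    expect_gte(f$contrast, 0)
    expect_gte(f$variance, 0)
    expect_true(f$homogeneity > 0 && f$homogeneity <= 1)
    expect_true(f$energy > 0 && f$energy <= 1)
    # relabel levels by reflection i -> L-1-i
    qr <- qmap_from_levels(L - 1L - lv, L = L)
    fr <- orientation_averaged_features(qr, ms_variance = FALSE)$averaged
    expect_equal(fr, f, tolerance = 1e-12)
  }
})

test_that("empty pair sets are flagged per orientation", {
  # two defined pixels stacked vertically: no horizontal pair exists
  lv <- matrix(NA_integer_, 3, 3)
  lv[1:2, 2] <- c(1L, 2L)
  q <- qmap_from_levels(lv, L = 4)
  expect_error(glcm(q, 0), "orientation 0")
  g <- glcm(q, 90)
  expect_equal(g$n_pairs, 1)
  avg <- orientation_averaged_features(q, ms_variance = FALSE)
  expect_false(0 %in% avg$orientations_used)
  # single defined pixel: every orientation is empty
  q1 <- qmap_from_levels(matrix(c(1L, NA, NA, NA), 2, 2), L = 4)
  expect_error(orientation_averaged_features(q1), "no orientation")
})

test_that("unnormalized matrices are rejected", {
  g <- glcm(qmap_from_levels(matrix(0:3, 2, 2), L = 4), 0)
  g$matrix <- g$matrix * 2
  expect_error(glcm_features(g), "normalized")
})
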