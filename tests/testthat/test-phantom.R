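test_that("control truth keeps the depth-wise stratification", {
  cfg <- flat_config("CONT", control_drift = c(0, 0, 0, 0))
  truth <- build_true_t2(cfg, "t0")
  v <- truth$true_t2[truth$mask]
  expect_true(all(v > cfg$t2_deep_baseline & v < cfg$t2_superficial_baseline))
  # column-wise: upper half hotter than lower half
  sup_mean <- mean(truth$true_t2[truth$layers$superficial])
  deep_mean <- mean(truth$true_t2[truth$layers$deep])
  expect_gt(sup_mean, deep_mean)
})

test_that("high-impact truth elevates over time and is monotone t0..t3", {
  cfg <- flat_config("HIMP")
  means <- vapply(cfg$time_points, function(tp) {
    tr <- build_true_t2(cfg, tp)
    mean(tr$true_t2[tr$mask])
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
  expect_gt(means["t3"], means["t0"])
})

test_that("band lesion mean elevation matches the analytic Gaussian integral", {
  a <- 20; w <- 0.15; ctr <- 0.5
  cfg <- flat_config("LIMP", band_amplitude = c(0, 0, 0, a),
                     band_width = w, band_center = ctr)
  t0 <- build_true_t2(cfg, "t0")
  t3 <- build_true_t2(cfg, "t3")
  measured <- mean(t3$true_t2[t3$mask] - t0$true_t2[t0$mask])
  analytic <- a * sqrt(2 * pi) * w * (pnorm((1 - ctr) / w) - pnorm(-ctr / w))
  expect_equal(measured, analytic, tolerance = 0.01)
})

test_that("band lesion outside the tissue is rejected", {
  expect_error(flat_config("LIMP", band_center = 1.4), "outside the tissue")
})

test_that("noiseless echoes follow the mono-exponential closed form", {
  cfg <- flat_config("CONT")
  truth <- build_true_t2(cfg, "t0")
  series <- synthesize_echoes(truth, echo_schedule(), cfg)
  px <- which(truth$mask, arr.ind = TRUE)[10, ]
  t2 <- truth$true_t2[px[1], px[2]]
  te <- series$echo_times
  expect_equal(series$pixels[px[1], px[2], ],
               cfg$s0 * exp(-te / t2), tolerance = 1e-12)
  # background stays zero without noise
  expect_equal(series$pixels[1, 1, ], rep(0, 12))
})

test_that("Rician background magnitudes follow the Rayleigh limit", {
  cfg <- phantom_config(group = "CONT", noise_model = "rician", snr = 50,
                        margin_px = 12, rng_seed = 7)
  truth <- build_true_t2(cfg, "t0")
  series <- synthesize_echoes(truth, echo_schedule(), cfg)
  bg <- series$pixels[rep(!truth$mask, 12)]
  sigma <- cfg$s0 / cfg$snr
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.05)
})

test_that("synthesis is bit-reproducible under a fixed seed", {
  cfg <- phantom_config(group = "HIMP", rng_seed = 11)
  truth <- build_true_t2(cfg, "t1")
  s1 <- synthesize_echoes(truth, echo_schedule(), cfg)
  s2 <- synthesize_echoes(truth, echo_schedule(), cfg)
  expect_identical(s1$pixels, s2$pixels)
})

test_that("snr must be positive when noise is enabled", {
  expect_error(phantom_config(snr = -1), "snr")
  expect_silent(phantom_config(snr = -1, noise_model = "none"))
})

test_that("cohort generation is deterministic and correctly shaped", {
  n <- c(CONT = 1, LIMP = 1, HIMP = 1)
  c1 <- generate_cohort(n, rng_seed = 5)
  c2 <- generate_cohort(n, rng_seed = 5)
  expect_identical(
    c1$samples$HIMP_01$time_points$t2$series$pixels,
    c2$samples$HIMP_01$time_points$t2$series$pixels)
  expect_equal(nrow(c1$metadata), 3 * 4)
  expect_setequal(unique(c1$metadata$group), c("CONT", "LIMP", "HIMP"))

  c3 <- generate_cohort(n, rng_seed = 6)
  expect_false(identical(
    c1$samples$CONT_01$time_points$t0$series$pixels,
    c3$samples$CONT_01$time_points$t0$series$pixels))
})

test_that("every sample starts with superficial above deep true T2", {
  cohort <- generate_cohort(c(CONT = 3, LIMP = 3, HIMP = 3), rng_seed = 9)
  for (smp in cohort$samples) {
    tr <- smp$time_points$t0$truth
    expect_gt(mean(tr$true_t2[tr$layers$superficial]),
              mean(tr$true_t2[tr$layers$deep]))
  }
})

test_that("cohort files round-trip through disk with metadata", {
  out <- withr::local_tempdir()
  cohort <- generate_cohort(c(CONT = 1), rng_seed = 3, time_points = "t0",
                            out_dir = out)
  meta <- read.csv(file.path(out, "metadata.csv"))
  expect_equal(nrow(meta), 1)
  series <- read_echo_series(meta$stack_path[1])
  orig <- cohort$samples$CONT_01$time_points$t0$series
  expect_equal(series$pixels, orig$pixels, tolerance = 1e-6)
  expect_equal(series$echo_times, orig$echo_times)
  mask <- read_mask(meta$mask_path[1])
  expect_identical(mask, cohort$samples$CONT_01$time_points$t0$truth$mask)
})
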