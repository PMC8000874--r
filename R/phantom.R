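#' Phantom configuration for a single cartilage sample
#'
#' Describes the geometry, baseline T2 stratification, lesion model, and noise
#' model of a synthetic cartilage cross-section imaged with a multi-echo
#' spin-echo sequence. Image convention throughout the package: row 1 is the
#' articular surface (superficial side); rows increase toward the deep layer
#' and the subchondral interface.
#'
#' The lesion model follows the qualitative morphology of impacted explants:
#' controls keep their depth-wise stratification apart from a small
#' multiplicative culture drift; low-energy impaction produces a band-like T2
#' elevation across the full sample width centred on the transitional zone;
#' high-energy impaction produces a diffuse 2D Gaussian elevation centred at
#' the impaction site whose amplitude and radius grow over time. Lesion fields
#' are additive in milliseconds.
#'
#' @param pixel_size In-plane pixel size in mm (default 0.23).
#' @param sample_width Cartilage sample width in mm (default 15).
#' @param cartilage_thickness Cartilage thickness in mm (default 2.5).
#' @param s0 Equilibrium signal amplitude in arbitrary units.
#' @param t2_superficial_baseline,t2_deep_baseline Baseline T2 (ms) at the
#'   articular surface and at the deep interface; T2 interpolates linearly with
#'   depth between them. Superficial must exceed deep.
#' @param group One of `"CONT"`, `"LIMP"`, `"HIMP"`.
#' @param time_points Ordered time-point labels (default `t0..t3`).
#' @param control_drift Fractional whole-map drift per time point (CONT only).
#' @param band_center Band lesion centre as a depth fraction in `[0, 1]`
#'   (0 = surface).
#' @param band_width Band Gaussian SD as a depth fraction.
#' @param band_amplitude Band peak elevation in ms per time point (LIMP only).
#' @param diffuse_center_col Diffuse lesion centre as a width fraction.
#' @param diffuse_center_depth Diffuse lesion centre as a depth fraction.
#' @param diffuse_radius_mm Lateral Gaussian SD in mm per time point (HIMP).
#' @param diffuse_depth_sd Depth Gaussian SD as a depth fraction.
#' @param diffuse_amplitude Diffuse peak elevation in ms per time point (HIMP).
#' @param undulation_amplitude_px Peak-to-trough surface undulation in pixels;
#'   exercises the per-column layer split on non-rectangular masks. Set 0 for
#'   a flat rectangular sample.
#' @param undulation_period_mm Undulation period in mm.
#' @param margin_px Background margin around the sample in pixels.
#' @param response_multiplier Multiplicative whole-map factor per time point
#'   (default all 1), applied after the lesion field; [generate_cohort()] draws
#'   these per sample to model between-sample response heterogeneity.
#' @param noise_model `"rician"` (magnitude MRI, default), `"gaussian"`, or
#'   `"none"`.
#' @param snr Signal-to-noise ratio at `s0`; the per-channel noise SD is
#'   `s0 / snr`.
#' @param rng_seed Optional integer seed making [synthesize_echoes()]
#'   deterministic.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(pixel_size = 0.23,
                           sample_width = 15,
                           cartilage_thickness = 2.5,
                           s0 = 1000,
                           t2_superficial_baseline = 40,
                           t2_deep_baseline = 27,
                           group = c("CONT", "LIMP", "HIMP"),
                           time_points = c("t0", "t1", "t2", "t3"),
                           control_drift = c(0, 0.033, 0.066, 0.054),
                           band_center = 0.5,
                           band_width = 0.15,
                           band_amplitude = c(0, 8, 20, 23),
                           diffuse_center_col = 0.5,
                           diffuse_center_depth = 0.4,
                           diffuse_radius_mm = c(0, 3.0, 4.5, 6.0),
                           diffuse_depth_sd = 0.35,
                           diffuse_amplitude = c(0, 13, 21, 40),
                           response_multiplier = rep(1, length(time_points)),
                           undulation_amplitude_px = 1,
                           undulation_period_mm = 5,
                           margin_px = 3,
                           noise_model = c("rician", "gaussian", "none"),
                           snr = 50,
                           rng_seed = NULL) {
  group <- match.arg(group)
  noise_model <- match.arg(noise_model)
  n_tp <- length(time_points)
  if (n_tp < 1L) stop("need at least one time point", call. = FALSE)
  if (pixel_size <= 0 || sample_width <= 0 || cartilage_thickness <= 0)
    stop("all lengths must be positive", call. = FALSE)
  if (t2_superficial_baseline <= 0 || t2_deep_baseline <= 0)
    stop("baseline T2 values must be positive", call. = FALSE)
  if (t2_superficial_baseline <= t2_deep_baseline)
    stop("superficial baseline T2 must exceed the deep baseline ",
         "(cartilage depth-wise stratification)", call. = FALSE)
  if (any(response_multiplier <= 0))
    stop("'response_multiplier' must be positive", call. = FALSE)
  for (nm in c("control_drift", "band_amplitude", "diffuse_radius_mm",
               "diffuse_amplitude", "response_multiplier")) {
    v <- get(nm)
    if (length(v) != n_tp)
      stop(sprintf("'%s' must have one value per time point (%d)", nm, n_tp),
           call. = FALSE)
  }
  if (any(band_amplitude < 0) || any(diffuse_amplitude < 0))
    stop("lesion amplitudes must be >= 0", call. = FALSE)
  if (band_center < 0 || band_center > 1)
    stop("'band_center' places the band outside the tissue (need [0, 1])",
         call. = FALSE)
  if (band_width <= 0 || diffuse_depth_sd <= 0)
    stop("lesion widths must be positive", call. = FALSE)
  if (snr <= 0 && noise_model != "none")
    stop("'snr' must be positive when noise is enabled", call. = FALSE)
  structure(
    list(pixel_size = pixel_size, sample_width = sample_width,
         cartilage_thickness = cartilage_thickness, s0 = s0,
         t2_superficial_baseline = t2_superficial_baseline,
         t2_deep_baseline = t2_deep_baseline,
         group = group, time_points = time_points,
         control_drift = control_drift,
         band_center = band_center, band_width = band_width,
         band_amplitude = band_amplitude,
         diffuse_center_col = diffuse_center_col,
         diffuse_center_depth = diffuse_center_depth,
         diffuse_radius_mm = diffuse_radius_mm,
         diffuse_depth_sd = diffuse_depth_sd,
         diffuse_amplitude = diffuse_amplitude,
         response_multiplier = response_multiplier,
         undulation_amplitude_px = undulation_amplitude_px,
         undulation_period_mm = undulation_period_mm,
         margin_px = margin_px,
         noise_model = noise_model, snr = snr, rng_seed = rng_seed),
    class = "phantom_config"
  )
}

# Sample geometry shared by mask and truth construction: per-column top row and
# height of the (vertically contiguous) cartilage run.
.phantom_geometry <- function(config) {
  width_px <- max(2L, round(config$sample_width / config$pixel_size))
  thick_px <- max(2L, round(config$cartilage_thickness / config$pixel_size))
  und <- as.integer(round(config$undulation_amplitude_px))
  margin <- as.integer(config$margin_px)
  nr <- margin + und + thick_px + margin
  nc <- margin + width_px + margin
  cols <- margin + seq_len(width_px)
  if (und > 0) {
    period_px <- config$undulation_period_mm / config$pixel_size
    # integer dip of the surface below its highest point, in 0..und
    offset <- round(und * (1 + sin(2 * pi * seq_len(width_px) / period_px)) / 2)
  } else {
    offset <- rep(0L, width_px)
  }
  top <- margin + 1L + as.integer(offset)
  bottom <- margin + und + thick_px       # deep interface is flat
  list(nr = nr, nc = nc, cols = cols, top = top,
       height = bottom - top + 1L, bottom = bottom, width_px = width_px)
}

#' Ground-truth T2 map of a phantom sample at one time point
#'
#' Builds the binary sample mask (a near-rectangular cross-section with
#' optional mild surface undulation), the true per-pixel T2 map, and the
#' superficial/deep layer masks. Inside the mask, T2 interpolates linearly
#' with the local depth fraction from the superficial to the deep baseline;
#' the group's lesion model for the requested time point is then applied
#' (see [phantom_config()]).
#'
#' @param config A [phantom_config()].
#' @param time_point A label present in `config$time_points`.
#' @return An object of class `ground_truth`: `true_t2` (matrix, ms, `NA`
#'   outside the mask), `mask` (logical matrix), `layers` (a `roi_layers`
#'   object), `depth` (matrix of depth fractions), plus the config and time
#'   point.
#' @export
build_true_t2 <- function(config, time_point) {
  stopifnot(inherits(config, "phantom_config"))
  ti <- match(time_point, config$time_points)
  if (is.na(ti))
    stop(sprintf("unknown time point '%s'", time_point), call. = FALSE)
  g <- .phantom_geometry(config)
  mask <- matrix(FALSE, g$nr, g$nc)
  depth <- matrix(NA_real_, g$nr, g$nc)
  xfrac <- matrix(NA_real_, g$nr, g$nc)
  for (k in seq_along(g$cols)) {
    rows <- g$top[k]:g$bottom
    mask[rows, g$cols[k]] <- TRUE
    depth[rows, g$cols[k]] <- (seq_along(rows) - 0.5) / g$height[k]
    xfrac[rows, g$cols[k]] <- (k - 0.5) / g$width_px
  }
  t2 <- config$t2_superficial_baseline +
    (config$t2_deep_baseline - config$t2_superficial_baseline) * depth
  if (config$group == "CONT") {
    t2 <- t2 * (1 + config$control_drift[ti])
  } else if (config$group == "LIMP") {
    a <- config$band_amplitude[ti]
    if (a > 0)
      t2 <- t2 + a * exp(-(depth - config$band_center)^2 /
                           (2 * config$band_width^2))
  } else {  # HIMP
    a <- config$diffuse_amplitude[ti]
    r <- config$diffuse_radius_mm[ti]
    if (a > 0 && r > 0) {
      x_mm <- (xfrac - config$diffuse_center_col) * config$sample_width
      t2 <- t2 + a * exp(-x_mm^2 / (2 * r^2) -
                           (depth - config$diffuse_center_depth)^2 /
                             (2 * config$diffuse_depth_sd^2))
    }
  }
  t2 <- t2 * config$response_multiplier[ti]
  t2[!mask] <- NA_real_
  structure(
    list(true_t2 = t2, mask = mask, layers = split_layers(mask),
         depth = depth, config = config, time_point = time_point),
    class = "ground_truth"
  )
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthesize a multi-echo spin-echo series from a ground-truth T2 map
#'
#' The noiseless signal follows the mono-exponential decay
#' `S(TE) = S0 * exp(-TE / T2)` per pixel inside the mask and is zero outside.
#' Rician noise replaces each value by the magnitude of a complex Gaussian
#' perturbation with per-channel SD `s0 / snr` (so background pixels follow a
#' Rayleigh distribution); Gaussian noise adds a single real channel.
#'
#' @param truth A [build_true_t2()] result.
#' @param schedule An [echo_schedule()].
#' @param config A [phantom_config()]; defaults to the truth's own config.
#' @param seed Optional seed overriding `config$rng_seed`.
#' @return An object of class `echo_series`: `pixels` (rows x cols x echoes
#'   array), `echo_times` (ms), `pixel_size` (mm), `sample_id`, `time_point`.
#' @export
synthesize_echoes <- function(truth, schedule = echo_schedule(),
                              config = truth$config, seed = config$rng_seed) {
  stopifnot(inherits(truth, "ground_truth"), inherits(schedule, "echo_schedule"))
  te <- echo_times(schedule)
  nr <- nrow(truth$true_t2); nc <- ncol(truth$true_t2)
  s <- array(0, dim = c(nr, nc, length(te)))
  inside <- truth$mask
  t2 <- truth$true_t2[inside]
  for (e in seq_along(te)) {
    plane <- matrix(0, nr, nc)
    plane[inside] <- config$s0 * exp(-te[e] / t2)
    s[, , e] <- plane
  }
  if (config$noise_model != "none") {
    if (config$snr <= 0)
      stop("'snr' must be positive when noise is enabled", call. = FALSE)
    sigma <- config$s0 / config$snr
    s <- .with_seed(seed, {
      n <- length(s)
      if (config$noise_model == "gaussian") {
        s + array(stats::rnorm(n, sd = sigma), dim = dim(s))
      } else {
        sqrt((s + array(stats::rnorm(n, sd = sigma), dim = dim(s)))^2 +
               array(stats::rnorm(n, sd = sigma), dim = dim(s))^2)
      }
    })
  }
  echo_series(pixels = s, echo_times = te, pixel_size = config$pixel_size,
              sample_id = "phantom", time_point = truth$time_point)
}

#' Multi-echo series container
#'
#' @param pixels rows x cols x echoes array of signal intensities (>= 0 for
#'   magnitude data; small negative values can arise from Gaussian test noise).
#' @param echo_times Echo times in ms, strictly increasing, one per slab.
#' @param pixel_size In-plane pixel size in mm.
#' @param sample_id,time_point Labels.
#' @return An object of class `echo_series`.
#' @export
echo_series <- function(pixels, echo_times, pixel_size = 0.23,
                        sample_id = "sample", time_point = "t0") {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  if (dim(pixels)[3] != length(echo_times))
    stop("echo dimension must match length(echo_times)", call. = FALSE)
  if (is.unsorted(echo_times, strictly = TRUE))
    stop("'echo_times' must be strictly increasing", call. = FALSE)
  structure(
    list(pixels = pixels, echo_times = as.numeric(echo_times),
         pixel_size = pixel_size, sample_id = sample_id,
         time_point = time_point),
    class = "echo_series"
  )
}

# Baseline T2 distributions (mean, SD in ms) used when drawing per-sample
# superficial/deep baselines for each exposure arm.
.baseline_distributions <- function() {
  list(
    CONT = c(sup_mean = 37.0, sup_sd = 6.4, deep_mean = 29.4, deep_sd = 5.1),
    LIMP = c(sup_mean = 38.2, sup_sd = 4.3, deep_mean = 26.1, deep_sd = 2.8),
    HIMP = c(sup_mean = 42.9, sup_sd = 5.8, deep_mean = 27.7, deep_sd = 6.0)
  )
}

#' Generate a longitudinal phantom cohort
#'
#' Draws per-sample superficial/deep baseline T2 from group-specific normal
#' distributions (truncated so that the superficial baseline stays above the
#' deep one and both stay positive), then builds the ground truth and the
#' noisy multi-echo series for every sample and time point. With `out_dir`
#' set, stacks are written as NIfTI float32 with JSON echo-time sidecars,
#' masks as PNG, and a metadata table as CSV.
#'
#' Two sources of between-sample longitudinal heterogeneity are drawn per
#' sample on top of the deterministic lesion model: a multiplicative
#' whole-map response jitter at every follow-up time point (SD `response_sd`,
#' emulating physiological and positioning variability between repeated
#' scans), and a lognormal lesion-severity factor (SD `lesion_scale_sd` on
#' the log scale, constant across time within a sample) scaling the band or
#' diffuse lesion amplitude. Set both to 0 for the deterministic model.
#'
#' @param n_per_group Named counts per exposure arm; default the study design
#'   `c(CONT = 7, LIMP = 14, HIMP = 14)`.
#' @param config Template [phantom_config()]; group and baselines are
#'   overridden per sample.
#' @param schedule An [echo_schedule()].
#' @param rng_seed Integer seed; the whole cohort is reproducible from it.
#' @param time_points Time points to simulate (default all in the template).
#' @param response_sd SD of the per-sample fractional response jitter at
#'   follow-up time points (default 0.05).
#' @param lesion_scale_sd Log-scale SD of the per-sample lesion-severity
#'   factor (default 0.3).
#' @param out_dir Optional output directory.
#' @return An object of class `phantom_cohort`: `samples` (list with per-sample
#'   `config`, and per-time-point `truth` and `series`), `metadata`
#'   (data.frame: sample_id, group, time_point, stack_path, mask_path, seed).
#' @export
generate_cohort <- function(n_per_group = c(CONT = 7, LIMP = 14, HIMP = 14),
                            config = phantom_config(),
                            schedule = echo_schedule(),
                            rng_seed = 1,
                            time_points = config$time_points,
                            response_sd = 0.05,
                            lesion_scale_sd = 0.3,
                            out_dir = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (any(n_per_group < 1)) stop("group counts must be >= 1", call. = FALSE)
  groups <- names(n_per_group)
  if (is.null(groups) || !all(groups %in% c("CONT", "LIMP", "HIMP")))
    stop("'n_per_group' must be named with CONT/LIMP/HIMP", call. = FALSE)
  if (!all(time_points %in% config$time_points))
    stop("'time_points' must be a subset of the template's time points",
         call. = FALSE)
  base <- .baseline_distributions()
  samples <- list()
  meta <- list()
  .with_seed(rng_seed, {
    idx <- 0L
    for (grp in groups) {
      for (i in seq_len(n_per_group[[grp]])) {
        idx <- idx + 1L
        sid <- sprintf("%s_%02d", grp, i)
        b <- base[[grp]]
        repeat {
          sup <- stats::rnorm(1, b["sup_mean"], b["sup_sd"])
          deep <- stats::rnorm(1, b["deep_mean"], b["deep_sd"])
          if (sup > deep + 1 && deep > 5) break
        }
        cfg <- config
        cfg$group <- grp
        cfg$t2_superficial_baseline <- sup
        cfg$t2_deep_baseline <- deep
        n_tp <- length(cfg$time_points)
        if (response_sd > 0 && n_tp > 1L) {
          jit <- 1 + stats::rnorm(n_tp - 1L, 0, response_sd)
          cfg$response_multiplier <- c(1, pmax(jit, 0.5))
        }
        if (lesion_scale_sd > 0) {
          ls <- exp(stats::rnorm(1, 0, lesion_scale_sd))
          cfg$band_amplitude <- cfg$band_amplitude * ls
          cfg$diffuse_amplitude <- cfg$diffuse_amplitude * ls
        }
        noise_seed <- sample.int(2147480000L, 1L)  # headroom for + k offsets
        cfg$rng_seed <- noise_seed
        tps <- list()
        for (k in seq_along(time_points)) {
          tp <- time_points[k]
          truth <- build_true_t2(cfg, tp)
          series <- synthesize_echoes(truth, schedule, cfg,
                                      seed = noise_seed + k)
          series$sample_id <- sid
          stack_path <- mask_path <- NA_character_
          if (!is.null(out_dir)) {
            dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
            stack_path <- file.path(out_dir, sprintf("%s_%s.nii.gz", sid, tp))
            mask_path <- file.path(out_dir, sprintf("%s_%s_mask.png", sid, tp))
            write_echo_series(series, stack_path)
            write_mask(truth$mask, mask_path)
          }
          tps[[tp]] <- list(truth = truth, series = series)
          meta[[length(meta) + 1L]] <- data.frame(
            sample_id = sid, group = grp, time_point = tp,
            stack_path = stack_path, mask_path = mask_path,
            seed = noise_seed + k, stringsAsFactors = FALSE)
        }
        samples[[sid]] <- list(config = cfg, time_points = tps)
      }
    }
  })
  metadata <- do.call(rbind, meta)
  if (!is.null(out_dir))
    utils::write.csv(metadata, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
  structure(list(samples = samples, metadata = metadata,
                 schedule = schedule, rng_seed = rng_seed),
            class = "phantom_cohort")
}
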