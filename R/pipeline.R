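#' Measure one sample at one time point
#'
#' Runs the per-sample analysis chain: T2 map fitting over the sample mask,
#' superficial/deep layer split, ROI summary statistics, and orientation-
#' averaged GLCM texture features for the whole sample and both layers.
#'
#' @param series An [echo_series()].
#' @param mask Logical whole-sample mask.
#' @param schedule An [echo_schedule()].
#' @param method Fit method, see [fit_t2_pixels()].
#' @param levels,range_mode,range_ms Quantization settings, see [quantize()].
#' @param rois Which ROIs to measure (subset of `whole`, `superficial`,
#'   `deep`).
#' @return A long data.frame with columns `sample_id`, `group` (`NA`, filled
#'   by the cohort driver), `time_point`, `roi`, `measure`, `value`; measures
#'   are `t2_mean`, `t2_sd`, `n_pixels`, `contrast`, `homogeneity`, `energy`,
#'   `variance`.
#' @export
measure_sample <- function(series, mask, schedule = echo_schedule(),
                           method = "loglinear", levels = 32,
                           range_mode = "fixed", range_ms = c(0, 120),
                           rois = c("whole", "superficial", "deep")) {
  map <- fit_t2_map(series, mask, schedule, method = method)
  layers <- split_layers(mask)
  roi_masks <- list(whole = layers$whole, superficial = layers$superficial,
                    deep = layers$deep)[rois]
  rows <- list()
  for (rn in names(roi_masks)) {
    roi <- roi_masks[[rn]]
    s <- roi_summary(map, roi, roi_name = rn)
    q <- quantize(map, roi, levels = levels, range_mode = range_mode,
                  range_ms = range_ms)
    f <- orientation_averaged_features(q)$averaged
    rows[[rn]] <- data.frame(
      sample_id = series$sample_id, group = NA_character_,
      time_point = series$time_point, roi = rn,
      measure = c("t2_mean", "t2_sd", "n_pixels",
                  "contrast", "homogeneity", "energy", "variance"),
      value = c(s$mean, s$sd, s$n_pixels,
                f$contrast, f$homogeneity, f$energy, f$variance),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Measure a whole phantom cohort
#'
#' Applies [measure_sample()] to every sample and time point of a
#' [generate_cohort()] result and assembles the long longitudinal
#' measurement table feeding [delta_table()] and the statistical battery.
#'
#' @param cohort A [generate_cohort()] result.
#' @param ... Passed to [measure_sample()].
#' @return Long data.frame: `sample_id`, `group`, `time_point`, `roi`,
#'   `measure`, `value`.
#' @export
cohort_measurements <- function(cohort, ...) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  rows <- list()
  for (sid in names(cohort$samples)) {
    smp <- cohort$samples[[sid]]
    for (tp in names(smp$time_points)) {
      el <- smp$time_points[[tp]]
      m <- measure_sample(el$series, el$truth$mask,
                          schedule = cohort$schedule, ...)
      m$group <- smp$config$group
      rows[[length(rows) + 1L]] <- m
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Group summary table of absolute values (study-table layout)
#'
#' Per ROI, measure, and group: `mean +/- SD` across samples at each time
#' point, the within-group Friedman p-value over time, and per-time-point
#' Kruskal-Wallis p-values across groups, with significance marked at
#' `alpha`.
#'
#' @param table Long measurement table from [cohort_measurements()].
#' @param measure Which measure to summarize (e.g. `"t2_mean"`).
#' @param rois ROIs to include.
#' @param alpha Significance level (default 0.01).
#' @return A list: `summary` (data.frame in the wide group x time layout) and
#'   `tests` (list of `test_result` objects keyed by cell).
#' @export
summarize_absolute <- function(table, measure = "t2_mean",
                               rois = c("whole", "superficial", "deep"),
                               alpha = 0.01) {
  .check_long_table(table)
  tps <- sort(unique(table$time_point))
  groups <- intersect(c("CONT", "LIMP", "HIMP"), unique(table$group))
  out <- list(); tests <- list()
  for (rn in rois) {
    for (g in groups) {
      d <- table[table$roi == rn & table$group == g &
                   table$measure == measure, ]
      cells <- vapply(tps, function(tp) {
        v <- d$value[d$time_point == tp]
        sprintf("%.1f ± %.1f", mean(v), stats::sd(v))
      }, character(1))
      fr <- friedman_dunn(table, g, rn, measure, alpha = alpha)
      tests[[paste("friedman", rn, g, sep = ".")]] <- fr
      out[[length(out) + 1L]] <- data.frame(
        roi = rn, group = g, t(cells),
        friedman_p = fr$p_value, significant = fr$significant,
        stringsAsFactors = FALSE)
    }
    kw <- vapply(tps, function(tp) {
      r <- kruskal_wallis(table, tp, rn, measure, alpha = alpha)
      tests[[paste("kruskal", rn, tp, sep = ".")]] <<- r
      r$p_value
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      roi = rn, group = "p-value (between groups)",
      t(stats::setNames(sprintf("%.3f", kw), tps)),
      friedman_p = NA_real_, significant = NA,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  names(summary)[3:(2 + length(tps))] <- tps
  list(summary = summary, tests = tests)
}

#' Group summary of relative changes with ANOVA + Tukey
#'
#' Summarizes per-sample relative changes (mean +/- SD of per-sample percent
#' change, one row per ROI x group) and compares the groups at each follow-up
#' time point by one-way ANOVA with Tukey's post hoc.
#'
#' @param deltas Output of [delta_table()].
#' @param measure Measure to summarize.
#' @param rois ROIs to include.
#' @param alpha Significance level (default 0.01).
#' @return A list: `summary` data.frame and `tests` (ANOVA `test_result`s
#'   keyed by `roi.time_point`).
#' @export
summarize_deltas <- function(deltas, measure = "t2_mean",
                             rois = c("whole", "superficial", "deep"),
                             alpha = 0.01) {
  tps <- sort(unique(deltas$time_point))
  groups <- intersect(c("CONT", "LIMP", "HIMP"), unique(deltas$group))
  out <- list(); tests <- list()
  for (rn in rois) {
    for (g in groups) {
      d <- deltas[deltas$roi == rn & deltas$group == g &
                    deltas$measure == measure, ]
      cells <- vapply(tps, function(tp) {
        v <- d$delta_pct[d$time_point == tp]
        sprintf("%.1f ± %.1f", mean(v), stats::sd(v))
      }, character(1))
      out[[length(out) + 1L]] <- data.frame(roi = rn, group = g, t(cells),
                                            stringsAsFactors = FALSE)
    }
    pv <- vapply(tps, function(tp) {
      d <- deltas[deltas$roi == rn & deltas$time_point == tp &
                    deltas$measure == measure, ]
      r <- anova_tukey(d$delta_pct, d$group, alpha = alpha)
      tests[[paste(rn, tp, sep = ".")]] <<- r
      r$p_value
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      roi = rn, group = "p-value (ANOVA)",
      t(stats::setNames(sprintf("%.3f", pv), tps)),
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  names(summary)[3:(2 + length(tps))] <- tps
  list(summary = summary, tests = tests)
}
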