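#' Relative change from baseline in percent
#'
#' `delta_x = ((value_tx / value_t0) - 1) * 100`. Scale-invariant: multiplying
#' both values by the same positive constant leaves the result unchanged.
#' A non-positive baseline makes the ratio meaningless; those entries return
#' `NA` with a warning.
#'
#' @param value_tx Value(s) at the follow-up time point.
#' @param value_t0 Baseline value(s); recycled as usual.
#' @return Relative change(s) in percent.
#' @examples
#' relative_change(40.3, 32.0)  # 25.94
#' relative_change(16, 32)      # -50
#' @export
relative_change <- function(value_tx, value_t0) {
  out <- (value_tx / value_t0 - 1) * 100
  bad <- !is.na(value_t0) & value_t0 <= 0
  if (any(bad)) {
    warning("non-positive baseline value(s); relative change undefined",
            call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

# Validate and subset a long measurement table
# (columns sample_id, group, time_point, roi, measure, value).
.check_long_table <- function(table) {
  need <- c("sample_id", "group", "time_point", "roi", "measure", "value")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("measurement table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- interaction(table$sample_id, table$time_point, table$roi,
                     table$measure, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (sample, time point, roi, measure) entries", call. = FALSE)
  invisible(table)
}

#' Per-sample relative changes from baseline
#'
#' Converts a long measurement table into per-sample relative changes
#' (percent) of every follow-up time point against the first time point.
#' Summaries over these per-sample changes are means of per-sample ratios --
#' not ratios of group means, which differ.
#'
#' @param table Long measurement table with columns `sample_id`, `group`,
#'   `time_point`, `roi`, `measure`, `value`.
#' @param baseline Baseline time-point label (default the first in sorted
#'   unique order, i.e. `"t0"` for the standard labels).
#' @return Long data.frame: `sample_id`, `group`, `roi`, `measure`,
#'   `time_point` (follow-up), `delta_pct`.
#' @export
delta_table <- function(table, baseline = NULL) {
  .check_long_table(table)
  tps <- sort(unique(table$time_point))
  if (is.null(baseline)) baseline <- tps[1]
  if (!baseline %in% tps) stop("baseline time point not present", call. = FALSE)
  base <- table[table$time_point == baseline, ]
  fu <- table[table$time_point != baseline, ]
  key <- function(d) paste(d$sample_id, d$roi, d$measure, sep = "\r")
  b <- base$value[match(key(fu), key(base))]
  data.frame(sample_id = fu$sample_id, group = fu$group, roi = fu$roi,
             measure = fu$measure, time_point = fu$time_point,
             delta_pct = relative_change(fu$value, b),
             stringsAsFactors = FALSE)
}

#' Friedman test with Dunn's post hoc over time points
#'
#' Within one exposure group, ROI, and measure, compares the repeated
#' measurements across time points by Friedman's rank test (samples as
#' blocks), followed by Dunn's z-based pairwise comparisons on the within-
#' block rank sums. Samples missing any time point are excluded with a
#' warning. Ties receive mid-ranks. Dunn p-values are reported unadjusted by
#' default; `p_adjust` accepts any [stats::p.adjust()] method.
#'
#' @param table Long measurement table (see [delta_table()]).
#' @param group,roi,measure Cell selectors.
#' @param alpha Significance level (default 0.01).
#' @param p_adjust Dunn p-value adjustment method (default `"none"`).
#' @return An object of class `test_result`.
#' @export
friedman_dunn <- function(table, group, roi, measure, alpha = 0.01,
                          p_adjust = "none") {
  .check_long_table(table)
  d <- table[table$group == group & table$roi == roi &
               table$measure == measure, ]
  if (nrow(d) == 0L) stop("no rows match the requested cell", call. = FALSE)
  tps <- sort(unique(d$time_point))
  wide <- stats::reshape(d[, c("sample_id", "time_point", "value")],
                         idvar = "sample_id", timevar = "time_point",
                         direction = "wide")
  m <- as.matrix(wide[, paste0("value.", tps), drop = FALSE])
  rownames(m) <- wide$sample_id
  complete <- stats::complete.cases(m)
  if (any(!complete))
    warning("excluding sample(s) with incomplete time series: ",
            paste(rownames(m)[!complete], collapse = ", "), call. = FALSE)
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 3L)
    stop("need at least 3 samples with complete time series", call. = FALSE)
  k <- ncol(m); n <- nrow(m)
  ranks <- t(apply(m, 1, rank))
  if (all(ranks == (k + 1) / 2)) {
    # every block fully tied: ranks carry no information; the tie-corrected
    # statistic is otherwise 0/0, so define it as 0
    posthoc <- data.frame(
      comparison = paste(tps[utils::combn(k, 2)[1, ]],
                         tps[utils::combn(k, 2)[2, ]], sep = " vs "),
      z = 0, p = 1, p_adj = 1, significant = FALSE, stringsAsFactors = FALSE)
    return(test_result("Friedman", statistic = 0, df = k - 1L, p_value = 1,
                       alpha = alpha, posthoc = posthoc, n = n,
                       cell = c(group = group, roi = roi, measure = measure)))
  }
  ft <- stats::friedman.test(m)
  # Dunn: mean within-block mid-ranks, z = diff / sqrt(k(k+1)/(6n))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  z <- (rbar[pairs[1, ]] - rbar[pairs[2, ]]) / se
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = p_adjust)
  posthoc <- data.frame(
    comparison = paste(tps[pairs[1, ]], tps[pairs[2, ]], sep = " vs "),
    z = as.numeric(z), p = p_raw, p_adj = p_adj,
    significant = p_adj <= alpha, stringsAsFactors = FALSE)
  test_result("Friedman", statistic = unname(ft$statistic),
              df = unname(ft$parameter), p_value = ft$p.value,
              alpha = alpha, posthoc = posthoc,
              n = n, cell = c(group = group, roi = roi, measure = measure))
}

#' Kruskal-Wallis test across exposure groups at one time point
#'
#' @param table Long measurement table.
#' @param time_point,roi,measure Cell selectors.
#' @param alpha Significance level (default 0.01).
#' @return A `test_result` (H statistic with tie correction, chi-square
#'   approximation), as computed by [stats::kruskal.test()].
#' @export
kruskal_wallis <- function(table, time_point, roi, measure, alpha = 0.01) {
  .check_long_table(table)
  d <- table[table$time_point == time_point & table$roi == roi &
               table$measure == measure, ]
  counts <- base::table(d$group)
  if (length(counts) < 2L || any(counts < 2L))
    stop("need >= 2 groups with >= 2 samples each", call. = FALSE)
  if (length(unique(d$value)) == 1L) {
    # fully tied data carry no rank information: H = 0 by convention
    # (the tie-corrected statistic is otherwise 0/0)
    return(test_result("Kruskal-Wallis", statistic = 0,
                       df = length(counts) - 1L, p_value = 1, alpha = alpha,
                       n = nrow(d),
                       cell = c(time_point = time_point, roi = roi,
                                measure = measure)))
  }
  kt <- stats::kruskal.test(d$value, factor(d$group))
  test_result("Kruskal-Wallis", statistic = unname(kt$statistic),
              df = unname(kt$parameter), p_value = kt$p.value, alpha = alpha,
              n = nrow(d),
              cell = c(time_point = time_point, roi = roi, measure = measure))
}

#' One-way ANOVA with Tukey's HSD post hoc
#'
#' Used for group-wise comparison of relative changes and of histology-change
#' scores. When every group has zero within-group variance the F statistic is
#' undefined (0/0) and the result is flagged with `NA` p-values.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length.
#' @param alpha Significance level (default 0.01).
#' @return A `test_result` with a Tukey HSD `posthoc` table.
#' @export
anova_tukey <- function(values, groups, alpha = 0.01) {
  groups <- factor(groups)
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  counts <- table(groups)
  if (length(counts) < 2L || any(counts < 2L))
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  wvar <- tapply(values, groups, stats::var)
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  fstat <- tab[["F value"]][1]
  pval <- tab[["Pr(>F)"]][1]
  if (!is.finite(fstat) || all(wvar == 0)) {
    return(test_result("one-way ANOVA", statistic = NA_real_,
                       df = c(tab[["Df"]][1], tab[["Df"]][2]),
                       p_value = NA_real_, alpha = alpha, n = length(values),
                       flagged = "zero within-group variance everywhere; F undefined"))
  }
  th <- stats::TukeyHSD(fit)$groups
  posthoc <- data.frame(comparison = rownames(th), diff = th[, "diff"],
                        p_adj = th[, "p adj"],
                        significant = th[, "p adj"] <= alpha,
                        row.names = NULL, stringsAsFactors = FALSE)
  test_result("one-way ANOVA", statistic = fstat,
              df = c(tab[["Df"]][1], tab[["Df"]][2]), p_value = pval,
              alpha = alpha, posthoc = posthoc, n = length(values))
}

#' Container for a statistical test outcome
#'
#' @param test Test name.
#' @param statistic Test statistic.
#' @param df Degrees of freedom.
#' @param p_value P-value in `[0, 1]` (or `NA` when flagged).
#' @param alpha Significance level; `significant` is `p_value <= alpha`.
#' @param posthoc Optional data.frame of pairwise post hoc comparisons.
#' @param n Number of observations (or blocks) used.
#' @param cell Optional named character vector identifying the analysis cell.
#' @param flagged Optional message describing a degenerate outcome.
#' @return An object of class `test_result`.
#' @export
test_result <- function(test, statistic, df, p_value, alpha = 0.01,
                        posthoc = NULL, n = NA_integer_, cell = NULL,
                        flagged = NULL) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p-value outside [0, 1]", call. = FALSE)
  structure(
    list(test = test, statistic = statistic, df = df, p_value = p_value,
         alpha = alpha, significant = !is.na(p_value) & p_value <= alpha,
         posthoc = posthoc, n = n, cell = cell, flagged = flagged),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cell <- if (!is.null(x$cell))
    paste0(" [", paste(names(x$cell), x$cell, sep = "=", collapse = ", "), "]")
  else ""
  cat(sprintf("%s%s: statistic = %.4g, p = %.4g%s\n", x$test, cell,
              x$statistic, x$p_value,
              if (isTRUE(x$significant)) sprintf(" (significant at %.2g)", x$alpha)
              else ""))
  if (!is.null(x$flagged)) cat("  flagged:", x$flagged, "\n")
  if (!is.null(x$posthoc)) {
    cat("  post hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
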