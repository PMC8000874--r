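test_that("relative change evaluates the baseline-ratio formula", {
  expect_equal(relative_change(42, 42), 0)
  expect_equal(relative_change(16, 32), -50)
  expect_equal(relative_change(40.3, 32.0), 25.94, tolerance = 1e-3)
  # scale invariance
  expect_equal(relative_change(3 * 40.3, 3 * 32.0),
               relative_change(40.3, 32.0), tolerance = 1e-12)
  expect_warning(out <- relative_change(10, 0), "baseline")
  expect_true(is.na(out))
})

test_that("per-sample delta tables use per-sample baselines", {
  vals <- rbind(c(32, 35.2, 40, 41.6),
                c(30, 30, 36, 27))
  tab <- toy_long_table(vals, groups = c("LIMP", "LIMP"))
  d <- delta_table(tab)
  expect_equal(nrow(d), 6)
  s1 <- d[d$sample_id == "s01", ]
  expect_equal(s1$delta_pct[s1$time_point == "t1"], 10, tolerance = 1e-12)
  expect_equal(s1$delta_pct[s1$time_point == "t3"], 30, tolerance = 1e-12)
  s2 <- d[d$sample_id == "s02", ]
  expect_equal(s2$delta_pct[s2$time_point == "t3"], -10, tolerance = 1e-12)
})

test_that("Friedman statistic matches an independent rank computation", {
  set.seed(41)
  vals <- matrix(rnorm(4 * 4, mean = 35, sd = 5), 4, 4)  # no ties a.s.
  tab <- toy_long_table(vals, groups = rep("HIMP", 4))
  res <- friedman_dunn(tab, "HIMP", "whole", "t2_mean")
  # brute-force oracle: within-block ranks, classical chi-square formula
  r <- t(apply(vals, 1, rank))
  n <- nrow(vals); k <- ncol(vals)
  chi2 <- 12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
  expect_equal(res$statistic, chi2, tolerance = 1e-10)
  expect_equal(res$df, k - 1)
  # Dunn z for one pair, by hand
  rbar <- colMeans(r)
  z01 <- (rbar[1] - rbar[2]) / sqrt(k * (k + 1) / (6 * n))
  ph <- res$posthoc
  expect_equal(ph$z[ph$comparison == "t0 vs t1"], unname(z01),
               tolerance = 1e-12)
  expect_equal(ph$p[ph$comparison == "t0 vs t1"],
               unname(2 * pnorm(-abs(z01))), tolerance = 1e-12)
})

test_that("constant time courses yield a null Friedman result", {
  vals <- matrix(40, 5, 4)
  tab <- toy_long_table(vals, groups = rep("CONT", 5))
  res <- friedman_dunn(tab, "CONT", "whole", "t2_mean")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
})

test_that("incomplete time series are excluded with a warning", {
  vals <- matrix(rnorm(16, 35), 4, 4)
  tab <- toy_long_table(vals, groups = rep("LIMP", 4))
  tab <- tab[!(tab$sample_id == "s04" & tab$time_point == "t2"), ]
  expect_warning(res <- friedman_dunn(tab, "LIMP", "whole", "t2_mean"), "s04")
  expect_equal(res$n, 3)
  tab2 <- tab[tab$sample_id %in% c("s01", "s02"), ]
  expect_error(friedman_dunn(tab2, "LIMP", "whole", "t2_mean"), "at least 3")
})

test_that("Kruskal-Wallis matches the hand rank formula and handles ties", {
  vals <- c(1.2, 2.4, 3.1, 4.7, 5.0, 6.3, 7.7, 8.1, 9.9)
  grp <- rep(c("CONT", "LIMP", "HIMP"), each = 3)
  tab <- data.frame(sample_id = paste0("s", 1:9), group = grp,
                    time_point = "t3", roi = "whole", measure = "t2_mean",
                    value = vals)
  res <- kruskal_wallis(tab, "t3", "whole", "t2_mean")
  r <- rank(vals)
  n <- length(vals)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, grp, function(x) sum(x)^2 / length(x))) - 3 * (n + 1)
  expect_equal(res$statistic, h, tolerance = 1e-10)
  # all observations identical: no rank information, H = 0 by convention
  tab$value <- 5
  res0 <- kruskal_wallis(tab, "t3", "whole", "t2_mean")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # degenerate group sizes
  expect_error(kruskal_wallis(tab[-(1:2), ], "t3", "whole", "t2_mean"),
               ">= 2")
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(43)
  vals <- matrix(rexp(20) + 1, 5, 4)
  tab <- toy_long_table(vals, groups = rep("HIMP", 5))
  tabT <- tab; tabT$value <- log(tab$value)^3 + exp(tab$value / 10)
  f1 <- friedman_dunn(tab, "HIMP", "whole", "t2_mean")
  f2 <- friedman_dunn(tabT, "HIMP", "whole", "t2_mean")
  expect_equal(f1$statistic, f2$statistic, tolerance = 1e-12)

  tab3 <- data.frame(sample_id = paste0("s", 1:12),
                     group = rep(c("CONT", "LIMP", "HIMP"), each = 4),
                     time_point = "t3", roi = "whole", measure = "t2_mean",
                     value = rexp(12))
  tab3T <- tab3; tab3T$value <- sqrt(tab3$value) + 7
  k1 <- kruskal_wallis(tab3, "t3", "whole", "t2_mean")
  k2 <- kruskal_wallis(tab3T, "t3", "whole", "t2_mean")
  expect_equal(k1$statistic, k2$statistic, tolerance = 1e-12)
})

test_that("one-way ANOVA F matches hand-computed sums of squares", {
  g1 <- c(10, 12, 14); g2 <- c(11, 15, 16); g3 <- c(20, 22, 27)
  vals <- c(g1, g2, g3)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- anova_tukey(vals, grp)
  gm <- mean(vals)
  ssb <- 3 * sum((tapply(vals, grp, mean) - gm)^2)
  ssw <- sum((vals - rep(tapply(vals, grp, mean), each = 3))^2)
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(nrow(res$posthoc), 3)
  # identical distributions in every group: F = 0
  res0 <- anova_tukey(rep(c(1, 2, 3), 3), grp)
  expect_equal(res0$statistic, 0)
  # zero within-group variance everywhere: F undefined, flagged
  resf <- anova_tukey(rep(5, 9), grp)
  expect_true(is.na(resf$p_value))
  expect_match(resf$flagged, "undefined")
  expect_error(anova_tukey(1:3, c("a", "b", "c")), ">= 2")
})

test_that("significance is flagged at the 0.01 level inclusively", {
  r <- test_result("toy", statistic = 1, df = 1, p_value = 0.01)
  expect_true(r$significant)
  r2 <- test_result("toy", statistic = 1, df = 1, p_value = 0.0101)
  expect_false(r2$significant)
  expect_error(test_result("toy", 1, 1, p_value = 1.2), "p-value")
})
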