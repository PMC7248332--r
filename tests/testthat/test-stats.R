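test_that("size-distribution fit recovers generating parameters", {
  set.seed(101)
  areas <- rnorm(500, 750, 100)
  fit <- fit_size_distribution(areas, bin = 100)
  expect_lt(abs(fit$par["mean"] - 750), 15)
  expect_lt(abs(fit$par["sd"] - 100), 3 * 100 / sqrt(2 * 499))
  expect_equal(fit$df, fit$n - 3L)
  expect_error(fit_size_distribution(rep(500, 50)), "degenerate")
  expect_error(fit_size_distribution(rnorm(5, 750, 100)), "at least 10")
})

test_that("doubling the counts doubles amplitude, not location or width", {
  pts <- data.frame(mid = seq(50, 1450, 100))
  pts$count <- 80 * exp(-(pts$mid - 700)^2 / (2 * 120^2))
  f1 <- fit_gaussian_points(pts)
  pts2 <- pts; pts2$count <- 2 * pts$count
  f2 <- fit_gaussian_points(pts2)
  expect_equal(f2$par[["amplitude"]], 2 * f1$par[["amplitude"]],
               tolerance = 1e-6)
  expect_equal(f2$par[["mean"]], f1$par[["mean"]], tolerance = 1e-6)
  expect_equal(f2$par[["sd"]], f1$par[["sd"]], tolerance = 1e-6)
})

test_that("extra sum-of-squares F-test arithmetic and degenerate cases", {
  r <- extra_ss_f_test(12, 8, 8, df_combined = 10)
  expect_equal(r$value, 2)
  expect_equal(r$p_value, pf(2, 2, 8, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$p_value, 0.1975309, tolerance = 1e-6)
  # identical datasets: shared curve fits both perfectly as well
  set.seed(7)
  a <- rnorm(300, 700, 130)
  res <- compare_size_distributions(a, a)
  expect_equal(res$test$value, 0, tolerance = 1e-6)
  expect_equal(res$test$p_value, 1, tolerance = 1e-6)
  expect_error(extra_ss_f_test(12, 8, 10, df_combined = 10), "exceed")
})

test_that("F-test detects a genuine shift between size distributions", {
  set.seed(31)
  a <- rnorm(400, 650, 120)
  b <- rnorm(400, 850, 120)
  res <- compare_size_distributions(a, b)
  expect_lt(res$test$p_value, 0.001)
  expect_lt(res$fit_a$par["mean"], res$fit_b$par["mean"])
})

test_that("F-test p-values are near-uniform under its null", {
  set.seed(55)
  x <- seq(50, 1450, 100)
  curve <- 120 * exp(-(x - 750)^2 / (2 * 150^2))
  pv <- replicate(200, {
    ya <- curve + rnorm(length(x), 0, 8)
    yb <- curve + rnorm(length(x), 0, 8)
    fa <- fit_gaussian_points(data.frame(mid = x, count = ya))
    fb <- fit_gaussian_points(data.frame(mid = x, count = yb))
    fc <- fit_gaussian_points(data.frame(mid = c(x, x), count = c(ya, yb)))
    extra_ss_f_test(fc$rss, fa$rss + fb$rss, fa$df + fb$df,
                    df_combined = fc$n - 3L)$p_value
  })
  # 3 binomial SE around 0.05 at 200 replicates
  expect_lt(abs(mean(pv < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("cumulative curves are ECDFs ending at 1", {
  cc <- cumulative_curve(c(1, 2, 3))
  expect_equal(cc$cum_fraction, c(1, 2, 3) / 3)
  single <- cumulative_curve(5)
  expect_equal(single$cum_fraction, 1)
  # stochastically larger sample: curve shifted right at every level
  set.seed(9)
  a <- rnorm(200, 600, 50); b <- a + 100
  qs <- seq(0.1, 0.9, 0.1)
  expect_true(all(quantile(b, qs) > quantile(a, qs)))
})

test_that("unpaired t-test on per-DRG percentages matches the closed form", {
  r <- compare_proportions(c(10, 12, 14), c(20, 22, 24))
  expect_equal(r$value, -6.123724, tolerance = 1e-6)
  expect_equal(r$df, 4)
  # closed-form pooled-variance oracle: 2 * pt(-|t|, df = 4)
  expect_equal(r$p_value, 2 * pt(-6.1237244, 4), tolerance = 1e-6)
  expect_equal(r$groups$mean, c(12, 22))
  # identical groups
  same <- compare_proportions(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$value, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_proportions(1, c(2, 3)), "at least 2")
  # antisymmetry and shift invariance
  a <- c(11, 14, 17, 13); b <- c(19, 22, 25, 21)
  expect_equal(compare_proportions(a, b)$value,
               -compare_proportions(b, a)$value)
  expect_equal(compare_proportions(a + 7, b + 7)$value,
               compare_proportions(a, b)$value, tolerance = 1e-12)
})

test_that("t-test type-I error is nominal", {
  set.seed(77)
  pv <- replicate(500, compare_proportions(rnorm(6, 50, 10),
                                           rnorm(6, 50, 10))$p_value)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("one-way ANOVA + Tukey flags the shifted group only", {
  set.seed(13)
  n <- 50
  vals <- c(rnorm(n, 10, 2), rnorm(n, 10 + 5 * 2, 2), rnorm(n, 10, 2))
  grp <- rep(c("sham_L4", "cuff_L4", "cuff_L5"), each = n)
  res <- compare_intensities(vals, grp)
  expect_lt(res$anova$p_value, 0.001)
  tk <- res$tukey
  p_l4 <- tk$p_adj[tk$contrast == "sham_L4-cuff_L4"]
  p_l5 <- tk$p_adj[tk$contrast == "cuff_L5-cuff_L4"]
  p_null <- tk$p_adj[tk$contrast == "sham_L4-cuff_L5"]
  expect_lt(p_l4, 0.001)
  expect_lt(p_l5, 0.001)
  expect_gt(p_null, 0.05)
  # degenerate constant input is flagged, not given a p-value
  flat <- compare_intensities(rep(3, 20), rep(c("a", "b"), each = 10))
  expect_true(flat$no_variance)
  expect_true(is.na(flat$anova$p_value))
  expect_error(compare_intensities(1:5, c("a", "a", "a", "a", "b")),
               "fewer than 2")
})

test_that("F and t statistics are invariant to constant offsets", {
  set.seed(3)
  x <- seq(50, 1450, 100)
  curve <- 100 * exp(-(x - 700)^2 / (2 * 140^2))
  ya <- curve + rnorm(length(x), 0, 5)
  yb <- curve + rnorm(length(x), 0, 5)
  fit_f <- function(ya, yb) {
    fa <- fit_gaussian_points(data.frame(mid = x, count = ya))
    fb <- fit_gaussian_points(data.frame(mid = x, count = yb))
    fc <- fit_gaussian_points(data.frame(mid = c(x, x), count = c(ya, yb)))
    extra_ss_f_test(fc$rss, fa$rss + fb$rss, fa$df + fb$df,
                    df_combined = fc$n - 3L)$value
  }
  # shifting the x-axis (areas) leaves the F statistic unchanged
  fa <- fit_gaussian_points(data.frame(mid = x + 100, count = ya))
  fb <- fit_gaussian_points(data.frame(mid = x + 100, count = yb))
  fc <- fit_gaussian_points(data.frame(mid = c(x, x) + 100, count = c(ya, yb)))
  f_shift <- extra_ss_f_test(fc$rss, fa$rss + fb$rss, fa$df + fb$df,
                             df_combined = fc$n - 3L)$value
  expect_equal(f_shift, fit_f(ya, yb), tolerance = 1e-6)
})
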