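#' Fit a scaled Gaussian to a soma-size histogram
#'
#' Bins the areas on a fixed grid (default 100 um^2 bins from 0) and fits
#' `count ~ A * exp(-(mid - mu)^2 / (2 * sigma^2))` by least squares
#' (Levenberg–Marquardt, moment-based starting values). This is the model
#' behind the size-distribution curves whose shifts are compared with the
#' extra sum-of-squares F-test.
#'
#' @param areas soma areas, um^2 (>= 10 values).
#' @param bin bin width, um^2.
#' @param breaks optional explicit break points (overrides `bin`); use a
#'   shared grid when two groups will be compared.
#' @return a `curve_fit`: list with `par` (amplitude, mean, sd), `rss`,
#'   `n` (number of histogram points), `df` (`n - 3`), `bins`
#'   (data.frame mid, count) and `fitted`.
#' @export
fit_size_distribution <- function(areas, bin = 100, breaks = NULL) {
  if (length(areas) < 10) stop_param("need at least 10 areas")
  if (is.null(breaks)) {
    if (bin <= 0) stop_param("bin must be > 0")
    breaks <- seq(0, ceiling(max(areas) / bin) * bin, by = bin)
  }
  if (stats::sd(areas) == 0)
    stop_param("degenerate input: all areas identical")
  h <- graphics::hist(areas, breaks = breaks, plot = FALSE)
  pts <- data.frame(mid = h$mids, count = h$counts)
  fit_gaussian_points(pts, start_from = areas)
}

#' Least-squares scaled-Gaussian fit to (x, y) points
#'
#' Fits `count ~ A * exp(-(mid - mu)^2 / (2 * sigma^2))` to a data.frame
#' of points. Used by [fit_size_distribution()] on histogram counts and
#' directly by null simulations that draw points from a shared curve with
#' iid Gaussian errors (the sampling model under which the extra
#' sum-of-squares F-test is exactly calibrated).
#' @param pts data.frame with columns `mid` (x) and `count` (y).
#' @param start_from optional raw sample whose moments seed the start
#'   values; otherwise weighted moments of the points are used.
#' @return a `curve_fit` (see [fit_size_distribution()]).
#' @export
fit_gaussian_points <- function(pts, start_from = NULL) {
  w <- pmax(pts$count, 0)
  mu0 <- if (!is.null(start_from)) mean(start_from) else
    sum(pts$mid * w) / max(sum(w), 1)
  sd0 <- if (!is.null(start_from)) stats::sd(start_from) else {
    v <- sum(w * (pts$mid - mu0)^2) / max(sum(w), 1)
    # floor keeps the start broad enough for a non-degenerate gradient
    sqrt(max(v, (diff(range(pts$mid)) / 10)^2))
  }
  a0 <- max(pts$count)
  fit <- minpack.lm::nlsLM(
    count ~ A * exp(-(mid - mu)^2 / (2 * sigma^2)),
    data = pts,
    start = list(A = a0, mu = mu0, sigma = sd0),
    lower = c(0, -Inf, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  structure(
    list(par = c(amplitude = unname(cf["A"]), mean = unname(cf["mu"]),
                 sd = abs(unname(cf["sigma"]))),
         rss = rss, n = nrow(pts), df = nrow(pts) - 3L,
         bins = pts, fitted = stats::fitted(fit)),
    class = "curve_fit"
  )
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit> Gaussian: A=%.2f, mean=%.1f, sd=%.1f (RSS %.2f, df %d)\n",
              x$par["amplitude"], x$par["mean"], x$par["sd"], x$rss, x$df))
  invisible(x)
}

comparison_result <- function(statistic, value, df, p, groups = NULL) {
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  structure(list(statistic = statistic, value = value, df = df,
                 p_value = p, groups = groups),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s = %.4g (df %s), p = %.4g\n",
              x$statistic, x$value, paste(round(x$df, 2), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' Extra sum-of-squares F-test for nested curve fits
#'
#' Tests "one curve describes both datasets" against "each dataset has its
#' own curve": `F = ((SS_c - SS_s) / (df_c - df_s)) / (SS_s / df_s)` with
#' p-value from the upper tail of `F(df_c - df_s, df_s)`. `SS_c`/`df_c`
#' come from the combined (shared-parameter) fit, `SS_s`/`df_s` from the
#' separate fits (summed SS, `df = n_points - 2 * n_parameters`).
#'
#' @param fit_combined a `curve_fit` (or a number, the combined SS).
#' @param df_combined combined df (taken from the fit when omitted).
#' @param ss_separate,df_separate summed SS and df of the separate fits.
#' @return a `comparison_result` with `value = F`, `df = c(df1, df2)`.
#' @export
extra_ss_f_test <- function(fit_combined, ss_separate, df_separate,
                            df_combined = NULL) {
  if (inherits(fit_combined, "curve_fit")) {
    ss_c <- fit_combined$rss
    df_c <- df_combined %||% fit_combined$df
  } else {
    ss_c <- fit_combined
    df_c <- df_combined
    if (is.null(df_c)) stop_param("df_combined required with a numeric SS")
  }
  if (df_c <= df_separate) stop_param("combined df must exceed separate df")
  if (ss_separate < 0) stop_param("SS must be non-negative")
  # the nested model cannot beat the richer one; tolerate optimizer jitter
  if (ss_c < ss_separate) {
    if ((ss_separate - ss_c) / max(ss_separate, 1) > 1e-6)
      stop_param("combined SS (%.6g) below separate SS (%.6g): fits inconsistent",
                 ss_c, ss_separate)
    ss_c <- ss_separate
  }
  df1 <- df_c - df_separate
  df2 <- df_separate
  f <- if (ss_separate == 0) {
    if (ss_c == ss_separate) 0 else Inf
  } else {
    ((ss_c - ss_separate) / df1) / (ss_separate / df2)
  }
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  comparison_result("F", f, c(df1, df2), p)
}

#' Compare two size distributions with the extra sum-of-squares F-test
#'
#' Fits scaled Gaussians to each group's histogram on a shared bin grid,
#' then to all histogram points pooled (one shared curve), and applies
#' [extra_ss_f_test()].
#' @param areas_a,areas_b soma areas of the two groups, um^2.
#' @param bin bin width, um^2.
#' @return list with `fit_a`, `fit_b`, `fit_combined` and `test`
#'   (a `comparison_result`).
#' @export
compare_size_distributions <- function(areas_a, areas_b, bin = 100) {
  top <- ceiling(max(areas_a, areas_b) / bin) * bin
  breaks <- seq(0, top, by = bin)
  fit_a <- fit_size_distribution(areas_a, breaks = breaks)
  fit_b <- fit_size_distribution(areas_b, breaks = breaks)
  pooled <- rbind(fit_a$bins, fit_b$bins)
  fit_c <- fit_gaussian_points(pooled, start_from = c(areas_a, areas_b))
  ss_s <- fit_a$rss + fit_b$rss
  df_s <- fit_a$df + fit_b$df
  test <- extra_ss_f_test(fit_c$rss, ss_s, df_s, df_combined = fit_c$n - 3L)
  list(fit_a = fit_a, fit_b = fit_b, fit_combined = fit_c, test = test)
}

#' Empirical cumulative size curve
#'
#' Right-continuous empirical CDF of the areas; the final value is 1.
#' @param areas numeric vector (>= 1 value).
#' @return data.frame with columns `area` (sorted unique values) and
#'   `cum_fraction`.
#' @export
cumulative_curve <- function(areas) {
  if (length(areas) < 1) stop_param("need at least one area")
  x <- sort(unique(areas))
  data.frame(area = x, cum_fraction = stats::ecdf(areas)(x))
}

#' Unpaired t-test on per-ganglion percentages
#'
#' Two-sample t-test comparing group-level observations — one value per
#' DRG section/ganglion, the experimental unit — defaulting to the
#' classical pooled-variance form; `var_equal = FALSE` gives the Welch
#' variant.
#' @param group_a,group_b numeric vectors (each length >= 2).
#' @param var_equal pool the variances (default `TRUE`).
#' @return a `comparison_result`; `groups` holds n, mean and SEM per group.
#' @export
compare_proportions <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_param("each group needs at least 2 observations")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  groups <- data.frame(
    group = c("a", "b"),
    n = c(length(group_a), length(group_b)),
    mean = c(mean(group_a), mean(group_b)),
    sem = c(sem(group_a), sem(group_b))
  )
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    df <- length(group_a) + length(group_b) - 2
    return(comparison_result("t", 0, df, 1, groups))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  comparison_result("t", unname(tt$statistic), unname(tt$parameter),
                    tt$p.value, groups)
}

#' One-way ANOVA with Tukey contrasts on per-cell intensities
#'
#' Compares background-corrected per-neuron intensities across groups
#' (e.g. condition x segment) with a one-way ANOVA followed by Tukey's
#' honestly-significant-difference pairwise comparisons; both are
#' delegated to [stats::aov()] / [stats::TukeyHSD()]. When every
#' observation is identical the variance is zero and the F statistic is
#' undefined; this degenerate case is flagged rather than reported as a
#' p-value.
#'
#' @param values numeric vector of per-neuron intensities.
#' @param groups group labels (same length; >= 2 non-empty groups, each
#'   with >= 2 observations).
#' @return list with `anova` (a `comparison_result`), `tukey` (data.frame
#'   of pairwise contrasts with Tukey-adjusted p-values) and `no_variance`
#'   (logical flag).
#' @export
compare_intensities <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_param("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 2))
    stop_param("group '%s' has fewer than 2 observations",
               names(sizes)[which(sizes < 2)[1]])
  summ <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  if (stats::sd(values) == 0) {
    return(list(
      anova = comparison_result("F", NA_real_, c(nlevels(groups) - 1,
                                                 length(values) - nlevels(groups)),
                                NA_real_, summ),
      tukey = NULL, no_variance = TRUE
    ))
  }
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  res <- comparison_result("F", an[["F value"]][1],
                           c(an[["Df"]][1], an[["Df"]][2]),
                           an[["Pr(>F)"]][1], summ)
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(anova = res, tukey = tukey, no_variance = FALSE)
}
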