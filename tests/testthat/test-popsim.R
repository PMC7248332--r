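test_that("sampling is deterministic and conserves counts", {
  p <- population_params()
  a <- sample_population(p, 100, seed = 42)
  b <- sample_population(p, 100, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a), 100)
  ct <- coexpression_table(a, source = "truth")
  expect_equal(sum(ct$count), 100)
  c2 <- sample_population(p, 100, seed = 43)
  expect_false(identical(a$soma_area, c2$soma_area))
})

test_that("degenerate all-'none' distribution yields no expression", {
  cp <- c(
    "none" = 1, "ASIC1a" = 0, "ASIC2b" = 0, "ASIC3" = 0,
    "ASIC1a+ASIC2b" = 0, "ASIC1a+ASIC3" = 0, "ASIC2b+ASIC3" = 0,
    "ASIC1a+ASIC2b+ASIC3" = 0)
  p <- population_params(coexpr_probs = cp)
  pop <- sample_population(p, 50, seed = 1)
  for (pr in DEFAULT_PROBES) {
    expect_true(all(pop[[paste0("truth_", pr)]] == 0L))
    expect_true(all(pop[[paste0("true_puncta_", pr)]] <= 2L))
  }
})

test_that("multinomial truth fractions recover their parameters", {
  p <- population_params(mode = "multinomial")
  pop <- sample_population(p, 2038, seed = 7)
  ct <- coexpression_table(pop, source = "truth")
  probs <- p$coexpr_probs[ct$combination]
  se <- sqrt(probs * (1 - probs) / 2038)
  expect_true(all(abs(ct$fraction - probs) <= 3 * se + 1e-12))
})

test_that("bernoulli truth fractions recover per-marker probabilities", {
  p <- single_class_params("NF200", p_expr = 0.73)
  pop <- sample_population(p, 1000, seed = 5)
  frac <- mean(pop$truth_ASIC3)
  expect_lt(abs(frac - 0.73), 3 * sqrt(0.73 * 0.27 / 1000))
  expect_true(all(pop$marker == "NF200"))
})

test_that("soma areas are positive, marker-dependent, probe-independent", {
  p <- population_params()
  pop <- sample_population(p, 3000, seed = 9)
  expect_true(all(pop$soma_area > 0))
  expect_gt(mean(pop$soma_area[pop$marker == "NF200"]),
            mean(pop$soma_area[pop$marker == "IB4"]))
  # conditional independence: area uncorrelated with expression state
  for (m in c("NF200", "CGRP")) {
    sel <- pop$marker == m
    r <- cor(pop$soma_area[sel], pop$truth_ASIC3[sel])
    expect_lt(abs(r), 3 / sqrt(sum(sel)))
  }
})

test_that("invalid parameters fail naming the offending entry", {
  expect_error(population_params(marker_proportions = c(
    NF200 = 0.5, CGRP = 0.5, IB4 = 0.2, unlabeled = -0.2
  )), "unlabeled")
  expect_error(population_params(marker_proportions = c(
    NF200 = 0.5, CGRP = 0.2, IB4 = 0.2, unlabeled = 0.2
  )), "sum to 1")
  cp <- c("none" = 0.5, "ASIC1a" = 0.6, "ASIC2b" = 0, "ASIC3" = 0,
          "ASIC1a+ASIC2b" = 0, "ASIC1a+ASIC3" = 0, "ASIC2b+ASIC3" = 0,
          "ASIC1a+ASIC2b+ASIC3" = 0)
  expect_error(population_params(coexpr_probs = cp), "sum to 1")
  sa <- data.frame(
    marker = DRG_MARKERS, mean = c(900, 420, 380, 500), sd = c(250, 0, 100, 150))
  expect_error(population_params(soma_area = sa), "CGRP")
  ce <- data.frame(segment = "L4", marker = "CGRP", probe = "ASIC9",
                   new_probability = 0.1)
  expect_error(population_params(condition_effects = ce), "ASIC9")
})

test_that("condition effects: sham identity, cuff shifts only listed cells", {
  ce <- data.frame(
    segment = c("L4", "L4"), marker = c("CGRP", "CGRP"),
    probe = c("ASIC1a", "ASIC3"),
    new_probability = c(0.05, 0.95),
    intensity_multiplier = c(NA, NA)
  )
  p <- population_params(mode = "bernoulli", condition_effects = ce)
  naive <- sample_population(p, 4000, seed = 21)
  sham <- apply_condition_effects(naive, p, "sham", "L4", seed = 22)
  expect_identical(sham$truth_ASIC1a, naive$truth_ASIC1a)
  expect_equal(unique(sham$condition), "sham")

  cuff_l4 <- apply_condition_effects(naive, p, "cuff", "L4", seed = 22)
  cgrp <- naive$marker == "CGRP"
  # targeted cells shift in the stated directions
  expect_lt(mean(cuff_l4$truth_ASIC1a[cgrp]), mean(naive$truth_ASIC1a[cgrp]))
  expect_gt(mean(cuff_l4$truth_ASIC3[cgrp]), mean(naive$truth_ASIC3[cgrp]))
  # untouched cells and probes are bitwise unchanged
  expect_identical(cuff_l4$truth_ASIC1a[!cgrp], naive$truth_ASIC1a[!cgrp])
  expect_identical(cuff_l4$truth_ASIC2b, naive$truth_ASIC2b)
  # a different segment leaves everything unchanged
  cuff_l5 <- apply_condition_effects(naive, p, "cuff", "L5", seed = 22)
  expect_identical(cuff_l5$truth_ASIC1a, naive$truth_ASIC1a)
})

test_that("intensity multiplier scales emitter brightness of positives", {
  ce <- data.frame(segment = "L4", marker = "CGRP+IB4", probe = "ASIC2b",
                   new_probability = NA, intensity_multiplier = 1.5)
  p <- population_params(mode = "bernoulli", condition_effects = ce)
  pop <- sample_population(p, 500, seed = 31)
  cuff <- apply_condition_effects(pop, p, "cuff", "L4", seed = 32)
  target <- cuff$marker %in% c("CGRP", "IB4") & cuff$truth_ASIC2b == 1L
  expect_true(all(cuff$eps_mult_ASIC2b[target] == 1.5))
  expect_true(all(cuff$eps_mult_ASIC2b[!target] == 1))
  # generating-distribution oracle: per-cell mean rendered intensity is
  # eps_mult-linear, so the cuff/sham ratio of means is exactly 1.5
  sham_mean <- mean(pop$true_puncta_ASIC2b[target] * 1)
  cuff_mean <- mean(cuff$true_puncta_ASIC2b[target] * cuff$eps_mult_ASIC2b[target])
  expect_equal(cuff_mean / sham_mean, 1.5, tolerance = 1e-12)
})

test_that("population CSV round-trips", {
  p <- population_params()
  pop <- sample_population(p, 20, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_population_csv(pop, f)
  back <- read_population_csv(f)
  expect_equal(attr(back, "probes"), DEFAULT_PROBES)
  expect_equal(back$soma_area, pop$soma_area, tolerance = 1e-12)
  expect_equal(back$truth_ASIC3, pop$truth_ASIC3)
})
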