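test_that("positivity rule: three or more puncta", {
  qc <- quant_config()
  expect_true(call_positive(3, qc))
  expect_false(call_positive(2, qc))
  expect_false(call_positive(0, qc))
  expect_equal(call_positive(c(0, 2, 3, 10), qc),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_error(call_positive(-1, qc), ">= 0")
})

test_that("circular ROI mean intensity is the disk average", {
  qc <- quant_config(roi_radius_px = 5)
  expect_equal(measure_mean_intensity(matrix(7, 30, 30), c(15, 15), qc), 7)
  img <- matrix(0, 40, 40)
  img[punctasim:::disk_mask(40, 40, 20, 20, 12)] <- 10  # disk covers the ROI
  expect_equal(measure_mean_intensity(img, c(20, 20), qc), 10)
  expect_error(measure_mean_intensity(matrix(1, 20, 20), c(3, 10), qc),
               "exits the image")
})

test_that("background is the mean of 3-5 puncta-free region means", {
  img <- matrix(0, 30, 90)
  img[, 1:30] <- 2; img[, 31:60] <- 4; img[, 61:90] <- 6
  qc <- quant_config(roi_radius_px = 5)
  centers <- list(c(15, 15), c(15, 45), c(15, 75))
  expect_equal(estimate_background(img, centers, qc), 4)
  expect_error(estimate_background(img, centers[1:2], qc),
               "three to five")
  # a region containing a detected punctum is rejected by name
  img2 <- img; img2[15, 45] <- 100
  sp <- detect_peaks(img2, 6, 1.5)
  expect_error(estimate_background(img2, centers, qc, spots = sp),
               "region 2")
})

test_that("background correction cancels any constant offset", {
  cfg <- sim_config(noise_sd = 0.5, seed = 14)
  rn <- punctasim:::render_single_neuron(500, 10, 1, cfg, seed = 14)
  sp <- detect_peaks(rn$img, 6, 1.5)
  qc <- quant_config()
  corr <- function(img) {
    measure_mean_intensity(img, rn$center, qc, radius_px = 20) -
      punctasim:::corner_background(img, sp, qc)
  }
  base <- corr(rn$img)
  shifted <- rn$img
  shifted$pixels <- shifted$pixels + 3.7
  expect_equal(corr(shifted), base, tolerance = 1e-9)
})

test_that("size classes split at 650 and 900 um^2 (closed middle)", {
  qc <- quant_config()
  expect_equal(as.character(classify_size(c(500, 700, 901), qc)),
               c("small", "medium", "large"))
  expect_equal(as.character(classify_size(c(650, 900), qc)),
               c("medium", "medium"))
  expect_error(classify_size(0, qc), "positive")
})

test_that("coexpression table partitions neurons over all combinations", {
  # one neuron per combination of three probes
  labs <- combo_labels(DEFAULT_PROBES)
  df <- data.frame(id = 1:8)
  for (p in DEFAULT_PROBES) {
    df[[paste0("called_", p)]] <- as.integer(vapply(
      strsplit(labs, "+", fixed = TRUE), function(s) p %in% s, logical(1)))
  }
  ct <- coexpression_table(df, DEFAULT_PROBES)
  expect_equal(ct$count, rep(1L, 8))
  expect_equal(sum(ct$fraction), 1, tolerance = 1e-12)
  # single probe, 4/10 positive
  one <- data.frame(id = 1:10, called_ASIC3 = c(rep(1, 4), rep(0, 6)))
  ct1 <- coexpression_table(one, "ASIC3")
  expect_equal(ct1$fraction[ct1$combination == "ASIC3"], 0.4)
  expect_equal(ct1$fraction[ct1$combination == "none"], 0.6)
  # a missing call names the neuron and probe
  bad <- df; bad$called_ASIC2b[3] <- NA
  expect_error(coexpression_table(bad, DEFAULT_PROBES), "ASIC2b")
})

test_that("marker percentages: arithmetic, empty classes undefined", {
  df <- data.frame(
    marker = c(rep("NF200", 10), rep("CGRP", 4)),
    called_ASIC3 = c(rep(1, 7), rep(0, 3), rep(0, 4))
  )
  tab <- marker_percentage_table(df, "ASIC3")
  expect_equal(tab$percent_positive[tab$marker == "NF200"], 70)
  expect_equal(tab$percent_positive[tab$marker == "CGRP"], 0)
  expect_true(is.na(tab$percent_positive[tab$marker == "IB4"]))
  expect_true(all(tab$percent_positive >= 0 & tab$percent_positive <= 100,
                  na.rm = TRUE))
})

test_that("soma area is pixel count times pixel area", {
  m <- matrix(0, 20, 20); m[1:10, 1:10] <- 1
  expect_equal(measure_soma_area(m, 0.63), 100 * 0.3969)
  expect_error(measure_soma_area(matrix(0, 5, 5), 0.63), "empty")
  # rasterized disk of requested area lands within one rim pixel-row
  px_um <- 0.2
  r_px <- sqrt(700 / pi) / px_um
  disk <- punctasim:::disk_mask(200, 200, 100, 100, r_px)
  band <- 2 * pi * r_px * px_um^2
  expect_lt(abs(measure_soma_area(disk, px_um) - 700), band)
})

test_that("end-to-end recovery of expression state at default noise", {
  p <- population_params()
  pop <- sample_population(p, 40, seed = 19)
  q <- quantify_population(pop, sim_config(seed = 19), quant_config(),
                           seed = 19)
  acc <- mean(unlist(lapply(DEFAULT_PROBES, function(pr) {
    q[[paste0("called_", pr)]] == q[[paste0("truth_", pr)]]
  })))
  expect_gte(acc, 0.95)
})

test_that("circular and whole-soma intensities agree on synthetic somata", {
  p <- population_params()
  pop <- sample_population(p, 40, seed = 23)
  cfg <- sim_config(noise_sd = 0.5, seed = 23)
  sec <- render_section(pop, cfg, probe = "ASIC3")
  res <- circular_vs_mask_intensity(sec, cfg)
  expect_gt(res$r, 0.9)
  expect_equal(nrow(res$table) + length(res$excluded), 40)
  # homogeneous intensity per soma gives exact agreement
  sec2 <- sec
  px <- sec2$probe_img$pixels * 0
  for (i in seq_len(40)) px[sec2$masks == i] <- i
  sec2$probe_img$pixels <- px
  res2 <- circular_vs_mask_intensity(sec2, cfg)
  expect_equal(res2$r, 1, tolerance = 1e-12)
  # correlation on fewer than 3 neurons is refused
  sec3 <- sec
  sec3$placement <- sec3$placement[1:2, ]
  expect_error(circular_vs_mask_intensity(sec3, cfg), "fewer than 3")
})
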