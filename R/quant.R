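#' Quantification configuration
#'
#' Parameters of the per-neuron quantification stage. Defaults follow the
#' reference protocol: a neuron is called positive when it shows three or
#' more puncta/cluster-like structures; per-cell intensity is the mean over
#' a circular ROI of 10 pixels (6.3 um) radius at 0.63 um/px; background is
#' the average of the mean intensities of 3–5 manually chosen puncta-free
#' regions; soma sizes are classified as small (< 650 um^2), medium
#' (650–900 um^2, both endpoints included) or large (> 900 um^2); size
#' histograms use 100 um^2 bins.
#'
#' @param positivity_min_puncta minimum puncta count to call a neuron
#'   positive.
#' @param roi_radius_px circular intensity-ROI radius, pixels.
#' @param px_size_um pixel size the ROI radius refers to, um.
#' @param n_background_regions allowed number of background regions (3–5).
#' @param size_small_max,size_medium_max size-class boundaries, um^2.
#' @param hist_bin histogram bin width, um^2.
#' @return an object of class `quant_config`.
#' @export
quant_config <- function(positivity_min_puncta = 3L, roi_radius_px = 10L,
                         px_size_um = 0.63, n_background_regions = 3L,
                         size_small_max = 650, size_medium_max = 900,
                         hist_bin = 100) {
  if (positivity_min_puncta < 1) stop_param("positivity_min_puncta must be >= 1")
  if (size_small_max <= 0 || size_small_max >= size_medium_max)
    stop_param("need 0 < size_small_max < size_medium_max")
  if (n_background_regions < 3 || n_background_regions > 5)
    stop_param("n_background_regions must be in [3, 5]")
  structure(list(positivity_min_puncta = as.integer(positivity_min_puncta),
                 roi_radius_px = roi_radius_px, px_size_um = px_size_um,
                 n_background_regions = as.integer(n_background_regions),
                 size_small_max = size_small_max,
                 size_medium_max = size_medium_max, hist_bin = hist_bin),
            class = "quant_config")
}

#' Positivity call from a puncta count
#'
#' A neuron is positive for a probe when it contains at least
#' `positivity_min_puncta` detected puncta (default 3).
#' @param puncta_count non-negative integer vector.
#' @param cfg a [quant_config()].
#' @return logical vector.
#' @export
call_positive <- function(puncta_count, cfg = quant_config()) {
  if (any(puncta_count < 0)) stop_param("puncta_count must be >= 0")
  puncta_count >= cfg$positivity_min_puncta
}

#' Mean intensity inside a circular ROI
#'
#' Arithmetic mean of the pixel values within the rasterized disk of radius
#' `radius_px` centered at `center` (row, col). The circle must lie fully
#' inside the image; neurons whose ROI exits the image are skipped upstream.
#' @param img `field_image` or matrix.
#' @param center numeric length-2, (row, col) in pixels.
#' @param cfg a [quant_config()].
#' @param radius_px ROI radius in pixels of *this* image (defaults to the
#'   configured radius).
#' @return mean intensity, i.u.
#' @export
measure_mean_intensity <- function(img, center, cfg = quant_config(),
                                   radius_px = cfg$roi_radius_px) {
  px <- as_pixels(img)
  r0 <- center[1]; c0 <- center[2]
  if (r0 - radius_px < 1 || r0 + radius_px > nrow(px) ||
      c0 - radius_px < 1 || c0 + radius_px > ncol(px))
    stop_param("circular ROI (radius %.1f px) exits the image", radius_px)
  m <- disk_mask(nrow(px), ncol(px), r0, c0, radius_px)
  mean(px[m])
}

#' Background estimate from puncta-free regions
#'
#' Averages the per-region mean intensities of 3–5 circular regions that
#' must be free of detected puncta; the result is subtracted from each
#' neuron's mean intensity on the same image.
#' @param img `field_image` or matrix.
#' @param centers list (or 2-column matrix) of (row, col) region centers.
#' @param cfg a [quant_config()].
#' @param spots optional `spot_set` on the same image used to verify the
#'   regions are puncta-free (computed with defaults when `NULL`).
#' @param radius_px background-region radius, pixels.
#' @return mean background, i.u.
#' @export
estimate_background <- function(img, centers, cfg = quant_config(),
                                spots = NULL, radius_px = cfg$roi_radius_px) {
  if (is.matrix(centers)) centers <- asplit(centers, 1)
  k <- length(centers)
  if (k < 3 || k > 5)
    stop_param("three to five background regions required (got %d)", k)
  px <- as_pixels(img)
  if (is.null(spots)) spots <- detect_peaks(px)
  means <- numeric(k)
  for (i in seq_len(k)) {
    ct <- centers[[i]]
    m <- disk_mask(nrow(px), ncol(px), ct[1], ct[2], radius_px)
    if (nrow(spots) && any(m[cbind(spots$row, spots$col)]))
      stop_param("background region %d contains detected puncta", i)
    means[i] <- mean(px[m])
  }
  mean(means)
}

#' Classify soma areas into size classes
#'
#' Small below `size_small_max`, medium on the closed interval
#' `[size_small_max, size_medium_max]`, large above. With defaults:
#' < 650 um^2 small, 650–900 medium, > 900 large.
#' @param area soma areas, um^2 (> 0).
#' @param cfg a [quant_config()].
#' @return factor with levels small/medium/large.
#' @export
classify_size <- function(area, cfg = quant_config()) {
  if (any(!is.finite(area) | area <= 0))
    stop_param("soma area must be positive")
  cls <- ifelse(area < cfg$size_small_max, "small",
                ifelse(area <= cfg$size_medium_max, "medium", "large"))
  factor(cls, levels = c("small", "medium", "large"))
}

#' Soma area of a mask component
#'
#' @param mask_component logical/0-1 matrix (one connected component).
#' @param px_size_um pixel size, um.
#' @return area in um^2 (pixel count times pixel area).
#' @export
measure_soma_area <- function(mask_component, px_size_um) {
  npix <- sum(mask_component != 0)
  if (npix == 0) stop_param("empty mask component")
  npix * px_size_um^2
}

called_matrix <- function(neurons, probes) {
  out <- sapply(probes, function(p) {
    col <- neurons[[paste0("called_", p)]]
    if (is.null(col)) stop_param("missing call for probe '%s'", p)
    if (anyNA(col)) {
      stop_param("neuron %s has no call for probe '%s'",
                 paste(neurons$id[is.na(col)][1]), p)
    }
    col != 0
  })
  matrix(out, nrow = nrow(neurons), dimnames = list(NULL, probes))
}

#' Co-expression combination table
#'
#' Partitions neurons into the `2^P` combinations of their per-probe
#' positivity calls and reports each combination's count and fraction of
#' the total (fractions sum to 1, counts to `n`).
#' @param neurons a `neuron_population` with `called_<probe>` columns
#'   (e.g. from [quantify_population()]), or any data.frame with them.
#' @param probes probes to combine (defaults to the population's probes).
#' @param source use `"called"` (default) or `"truth"` columns.
#' @return data.frame with columns `combination`, `count`, `fraction`,
#'   covering every combination (including empty ones).
#' @export
coexpression_table <- function(neurons, probes = attr(neurons, "probes"),
                               source = c("called", "truth")) {
  source <- match.arg(source)
  probes <- probes %||% DEFAULT_PROBES
  m <- if (source == "called") called_matrix(neurons, probes) else
    sapply(probes, function(p) neurons[[paste0("truth_", p)]] != 0)
  m <- matrix(m, nrow = nrow(neurons), dimnames = list(NULL, probes))
  lab <- apply(m, 1, function(row) {
    s <- probes[row]
    if (length(s) == 0) "none" else paste(s, collapse = "+")
  })
  labs <- combo_labels(probes)
  counts <- table(factor(lab, levels = labs))
  data.frame(combination = labs,
             count = as.integer(counts),
             fraction = as.numeric(counts) / nrow(neurons),
             row.names = NULL)
}

#' Percent of each marker class positive for a probe
#'
#' For each marker class, 100 times the number of positive calls over the
#' class size; empty classes are reported as `NA` (undefined), not 0.
#' @param neurons a data.frame with `marker` and `called_<probe>` columns.
#' @param probe probe name.
#' @return data.frame with columns `marker`, `n`, `n_positive`,
#'   `percent_positive`.
#' @export
marker_percentage_table <- function(neurons, probe) {
  col <- neurons[[paste0("called_", probe)]]
  if (is.null(col)) stop_param("missing call column for probe '%s'", probe)
  out <- lapply(DRG_MARKERS, function(m) {
    sel <- neurons$marker == m
    n <- sum(sel)
    np <- sum(col[sel] != 0)
    data.frame(marker = m, n = n, n_positive = np,
               percent_positive = if (n > 0) 100 * np / n else NA_real_)
  })
  do.call(rbind, out)
}

# Default per-neuron rendering: one soma per small field, padded so the PSF
# never clips and corner background regions stay clear of the soma.
render_single_neuron <- function(area_um2, true_puncta, eps_mult, cfg,
                                 seed, bg_margin_px = 24L) {
  px_um <- cfg$pixel_size / 1000
  radius_px <- sqrt(area_um2 / pi) / px_um
  s <- omega0_px(cfg)
  kpad <- max(1L, as.integer(ceiling(4 * s)))
  half <- ceiling(radius_px) + bg_margin_px
  npx <- 2L * half + 1L
  center <- half + 1
  counts <- matrix(0, npx, npx)
  withr::with_seed(seed, {
    if (true_puncta > 0) {
      rad <- radius_px * sqrt(stats::runif(true_puncta))
      th <- stats::runif(true_puncta, 0, 2 * pi)
      row <- pmin(pmax(round(center + rad * sin(th)), 1), npx)
      col <- pmin(pmax(round(center + rad * cos(th)), 1), npx)
      for (j in seq_len(true_puncta))
        counts[row[j], col[j]] <- counts[row[j], col[j]] + eps_mult
    }
  })
  img <- psf_render(counts, cfg)
  img <- add_noise(img, cfg, seed = seed)
  center_out <- center + img$pad_px
  mask <- disk_mask(nrow(img$pixels), ncol(img$pixels),
                    center_out, center_out, radius_px + 1)
  list(img = img, mask = mask, center = c(center_out, center_out),
       radius_px = radius_px, kpad = kpad)
}

#' Run the full per-neuron quantification on a simulated population
#'
#' The end-to-end pipeline: for every neuron and probe, its soma is
#' rendered as an isolated field (its `true_puncta_<probe>` emitters placed
#' uniformly in the soma disk, PSF-convolved, noise added), puncta are
#' detected as thresholded local maxima with minimum separation omega0,
#' counted inside the soma mask, and the >= 3-puncta rule produces the
#' positivity call. Optionally the background-corrected mean intensity is
#' measured with a centered circular ROI (physical radius
#' `roi_radius_px * px_size_um` from `qcfg`, converted to this image's
#' pixel grid and clipped to the soma radius for very small cells);
#' background comes from the image corners, verified puncta-free.
#'
#' @param pop a `neuron_population` from [sample_population()].
#' @param cfg a [sim_config()].
#' @param qcfg a [quant_config()].
#' @param seed integer master seed.
#' @param measure_intensity also fill `intensity_<probe>` columns (slower).
#' @return `pop` with added per-probe columns `puncta_<probe>` (detected
#'   count in the soma), `called_<probe>` (0/1) and, when requested,
#'   `intensity_<probe>` (background-corrected mean ROI intensity, i.u.).
#' @export
quantify_population <- function(pop, cfg = sim_config(),
                                qcfg = quant_config(), seed = cfg$seed,
                                measure_intensity = FALSE) {
  probes <- attr(pop, "probes") %||% DEFAULT_PROBES
  n <- nrow(pop)
  px_um <- cfg$pixel_size / 1000
  roi_um <- qcfg$roi_radius_px * qcfg$px_size_um
  min_sep <- omega0_px(cfg)
  for (p in probes) {
    pop[[paste0("puncta_", p)]] <- NA_integer_
    pop[[paste0("called_", p)]] <- NA_integer_
    if (measure_intensity) pop[[paste0("intensity_", p)]] <- NA_real_
  }
  for (i in seq_len(n)) {
    for (p in probes) {
      s <- derive_seed(seed, sprintf("neuron_%d_%s", i, p))
      rn <- render_single_neuron(
        pop$soma_area[i], pop[[paste0("true_puncta_", p)]][i],
        pop[[paste0("eps_mult_", p)]][i] %||% 1, cfg, s
      )
      spots <- detect_peaks(rn$img, threshold = cfg$detect_threshold,
                            min_separation = min_sep)
      cnt <- count_puncta_in_roi(spots, rn$mask)
      pop[[paste0("puncta_", p)]][i] <- cnt
      pop[[paste0("called_", p)]][i] <-
        as.integer(call_positive(cnt, qcfg))
      if (measure_intensity) {
        roi_px <- min(roi_um / px_um, rn$radius_px)
        sig <- measure_mean_intensity(rn$img, rn$center, qcfg,
                                      radius_px = roi_px)
        bg <- corner_background(rn$img, spots, qcfg)
        pop[[paste0("intensity_", p)]][i] <- sig - bg
      }
    }
  }
  pop
}

# Background from the corners of a single-neuron field (always outside the
# soma by construction); regions are verified puncta-free.
corner_background <- function(img, spots, qcfg, radius_px = 8) {
  px <- as_pixels(img)
  inset <- radius_px + 2
  corners <- list(c(inset, inset),
                  c(inset, ncol(px) - inset),
                  c(nrow(px) - inset, inset),
                  c(nrow(px) - inset, ncol(px) - inset))
  ok <- Filter(function(ct) {
    m <- disk_mask(nrow(px), ncol(px), ct[1], ct[2], radius_px)
    !(nrow(spots) && any(m[cbind(spots$row, spots$col)]))
  }, corners)
  if (length(ok) < 3)
    stop_param("fewer than three puncta-free background regions available")
  estimate_background(img, ok[seq_len(min(length(ok), qcfg$n_background_regions))],
                      qcfg, spots = spots, radius_px = radius_px)
}

#' Compare circular-ROI and whole-soma intensity measurements
#'
#' On a rendered section with ground-truth masks, measures each neuron's
#' mean probe intensity twice — over a centered circular ROI and over its
#' full soma mask — and reports the paired values with their Pearson
#' correlation. Neurons whose circle is not fully contained in their soma
#' are flagged and excluded.
#'
#' @param section output of [render_section()].
#' @param cfg the [sim_config()] used to render it.
#' @param qcfg a [quant_config()].
#' @return list with `table` (id, circular, mask), `r` (Pearson
#'   correlation) and `excluded` (ids dropped).
#' @export
circular_vs_mask_intensity <- function(section, cfg, qcfg = quant_config()) {
  px <- as_pixels(section$probe_img)
  px_um <- cfg$pixel_size / 1000
  roi_px <- qcfg$roi_radius_px * qcfg$px_size_um / px_um
  pl <- section$placement
  rows <- list(); excluded <- integer(0)
  for (i in seq_len(nrow(pl))) {
    circ <- disk_mask(nrow(px), ncol(px), pl$row_px[i], pl$col_px[i],
                      roi_px)
    soma <- section$masks == i
    if (any(circ & !soma)) {
      excluded <- c(excluded, pl$id[i])
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = pl$id[i], circular = mean(px[circ]), mask = mean(px[soma])
    )
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 3)
    stop_param("fewer than 3 neurons available for correlation")
  r <- if (stats::sd(tab$circular) == 0 || stats::sd(tab$mask) == 0) 1
  else stats::cor(tab$circular, tab$mask)
  list(table = tab, r = r, excluded = excluded)
}
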