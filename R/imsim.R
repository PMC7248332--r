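#' Gaussian point-spread-function model
#'
#' The confocal PSF is modelled as a 2-D Gaussian
#' `PSF(x, y) = I0 * exp(-2 (x^2 + y^2) / omega0^2)`, where `omega0` is the
#' e^-2 radius. For rendering, the kernel is normalized to unit sum so that
#' the integrated intensity contributed by one emitter is exactly
#' `epsilon * pi * (omega0 / pixel_size)^2` intensity units; `I0` is kept
#' only as metadata of the un-normalized form.
#'
#' @param omega0 e^-2 radius of the Gaussian, in nm (default 300).
#' @param I0 peak amplitude of the un-normalized kernel (metadata).
#' @return an object of class `psf_model`.
#' @export
psf_model <- function(omega0 = 300, I0 = 1) {
  if (!is.numeric(omega0) || omega0 <= 0)
    stop_param("omega0 must be > 0")
  structure(list(omega0 = omega0, I0 = I0), class = "psf_model")
}

#' Simulation configuration
#'
#' Holds the physical and detection parameters of the puncta-image
#' simulation. Defaults follow the reference simulation: mean per-particle
#' intensity `epsilon = 100` i.u., `200 x 200` nm pixels, `omega0 = 300` nm
#' (so 1.5 pixels), a circular ROI of 25 um diameter emulating an average
#' DRG soma, and a detection threshold of 6 i.u. The additive Gaussian
#' noise defaults to 1 i.u.; it must stay well below the single-punctum
#' peak (2 * epsilon) for the threshold to be meaningful.
#'
#' @param epsilon mean intensity counts per particle (i.u.).
#' @param pixel_size pixel pitch, nm.
#' @param psf a [psf_model()].
#' @param roi_diameter simulated circular ROI diameter, um.
#' @param density puncta per um^2.
#' @param noise_sd standard deviation of additive Gaussian noise, i.u.
#' @param detect_threshold local-maximum amplitude threshold, i.u.
#' @param seed integer master seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(epsilon = 100, pixel_size = 200, psf = psf_model(),
                       roi_diameter = 25, density = 1, noise_sd = 1,
                       detect_threshold = 6, seed = 1L) {
  cfg <- structure(
    list(epsilon = epsilon, pixel_size = pixel_size, psf = psf,
         roi_diameter = roi_diameter, density = density,
         noise_sd = noise_sd, detect_threshold = detect_threshold,
         seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$pixel_size <= 0) stop_param("pixel_size must be > 0")
  if (cfg$roi_diameter <= 0) stop_param("roi_diameter must be > 0")
  if (cfg$density < 0) stop_param("density must be >= 0")
  if (cfg$detect_threshold <= 0) stop_param("detect_threshold must be > 0")
  if (cfg$noise_sd < 0) stop_param("noise_sd must be >= 0")
  if (!inherits(cfg$psf, "psf_model")) stop_param("psf must be a psf_model")
  invisible(cfg)
}

# omega0 expressed in pixels.
omega0_px <- function(cfg) cfg$psf$omega0 / cfg$pixel_size

# Integrated intensity of one emitter, i.u. (unit-sum kernel normalization).
single_punctum_intensity <- function(cfg) {
  cfg$epsilon * pi * omega0_px(cfg)^2
}

#' Place point emitters uniformly in the circular ROI
#'
#' The number of emitters is Poisson with mean `density * pi * r^2` (`r` the
#' ROI radius); positions are uniform over the disk and may coincide.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (defaults to the config seed).
#' @return data.frame with columns `x_um`, `y_um` (coordinates relative to
#'   the ROI center).
#' @export
place_emitters <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  r <- cfg$roi_diameter / 2
  withr::with_seed(derive_seed(seed, "place_emitters"), {
    n <- stats::rpois(1, cfg$density * pi * r^2)
    rad <- r * sqrt(stats::runif(n))
    theta <- stats::runif(n, 0, 2 * pi)
  })
  data.frame(x_um = rad * cos(theta), y_um = rad * sin(theta))
}

#' Bin emitters into an integer count matrix
#'
#' Grid covers the ROI bounding box at the configured pixel size; entry
#' (i, j) counts the emitters whose position falls in that pixel, so the
#' matrix sum equals the number of emitters. An optional `weights` vector
#' accumulates per-emitter brightness multipliers instead of unit counts.
#'
#' @param positions data.frame from [place_emitters()].
#' @param cfg a [sim_config()].
#' @param weights optional per-emitter weights (default 1).
#' @return numeric matrix (rows = y, cols = x).
#' @export
render_counts <- function(positions, cfg, weights = NULL) {
  px_um <- cfg$pixel_size / 1000
  npx <- ceiling(cfg$roi_diameter / px_um)
  counts <- matrix(0, npx, npx)
  if (nrow(positions)) {
    half <- npx * px_um / 2
    col <- pmin(pmax(floor((positions$x_um + half) / px_um) + 1, 1), npx)
    row <- pmin(pmax(floor((positions$y_um + half) / px_um) + 1, 1), npx)
    w <- weights %||% rep(1, nrow(positions))
    lin <- (col - 1L) * npx + row
    agg <- rowsum(w, lin)
    counts[as.integer(rownames(agg))] <- agg[, 1]
  }
  counts
}

# Discrete Gaussian kernel with e^-2 radius s (pixels), truncated at 4 s and
# normalized to unit sum; truncation holds < 1e-6 of the mass.
gaussian_kernel <- function(s) {
  r <- max(1L, as.integer(ceiling(4 * s)))
  g <- exp(-2 * (-r:r)^2 / s^2)
  k <- outer(g, g)
  k / sum(k)
}

# Full 2-D convolution with zero boundary via vectorized shift-and-add.
conv2_shift <- function(mat, kernel) {
  nr <- nrow(mat); nc <- ncol(mat)
  kr <- (nrow(kernel) - 1L) / 2L; kc <- (ncol(kernel) - 1L) / 2L
  out <- matrix(0, nr + 2L * kr, nc + 2L * kc)
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      kv <- kernel[i, j]
      if (kv == 0) next
      out[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc)] <-
        out[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc)] + kv * mat
    }
  }
  out
}

# Same result as conv2_shift but adding one kernel patch per occupied pixel;
# cheaper when few pixels are occupied.
conv2_splat <- function(mat, kernel) {
  nr <- nrow(mat); nc <- ncol(mat)
  kr <- (nrow(kernel) - 1L) / 2L; kc <- (ncol(kernel) - 1L) / 2L
  out <- matrix(0, nr + 2L * kr, nc + 2L * kc)
  nz <- which(mat != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(nz))) {
    r <- nz[k, 1]; c <- nz[k, 2]
    out[r + 0:(2L * kr), c + 0:(2L * kc)] <-
      out[r + 0:(2L * kr), c + 0:(2L * kc)] + mat[r, c] * kernel
  }
  out
}

#' Render a count matrix through the Gaussian PSF
#'
#' Each occupied pixel's count is multiplied by
#' `epsilon * pi * (omega0 / pixel_size)^2` and convolved with the unit-sum
#' Gaussian kernel, so one isolated emitter integrates to exactly that
#' value and peaks at ~`2 * epsilon`. The returned image is padded by the
#' kernel radius on every side (`pad_px` attribute) so no emitter mass is
#' clipped; total image intensity is therefore exactly linear in the number
#' of emitters.
#'
#' @param counts matrix from [render_counts()].
#' @param cfg a [sim_config()].
#' @param channel channel label stored on the image.
#' @return a `field_image`: list with `pixels` (matrix), `pixel_size` (nm),
#'   `pad_px`, `channel` and `meta`.
#' @export
psf_render <- function(counts, cfg, channel = "probe") {
  validate_sim_config(cfg)
  if (any(counts < 0)) stop_param("counts must be non-negative")
  s <- omega0_px(cfg)
  if (s < 0.5)
    warning("PSF e^-2 radius below half a pixel: kernel is under-sampled")
  kernel <- gaussian_kernel(s)
  scaled <- counts * single_punctum_intensity(cfg)
  nnz <- sum(counts != 0)
  px <- if (nnz * length(kernel) < length(counts) * 4) {
    conv2_splat(scaled, kernel)
  } else {
    conv2_shift(scaled, kernel)
  }
  field_image(px, cfg$pixel_size, pad_px = (nrow(kernel) - 1L) / 2L,
              channel = channel, meta = list(seed = cfg$seed))
}

#' Construct a field image container
#' @param pixels numeric matrix (rows = y, cols = x).
#' @param pixel_size nm per pixel.
#' @param pad_px padding added around the source grid by PSF rendering.
#' @param channel channel label.
#' @param meta provenance list.
#' @return object of class `field_image`.
#' @export
field_image <- function(pixels, pixel_size, pad_px = 0L, channel = "probe",
                        meta = list()) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)))
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 pad_px = as.integer(pad_px), channel = channel, meta = meta),
            class = "field_image")
}

as_pixels <- function(img) {
  if (inherits(img, "field_image")) img$pixels else as.matrix(img)
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> %d x %d px @ %g nm, channel '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$channel))
  invisible(x)
}

#' Add detection noise
#'
#' Independent zero-mean Gaussian noise of standard deviation
#' `cfg$noise_sd` is added to every pixel.
#' @param img a `field_image` (or plain matrix).
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return image of the input type with noise added.
#' @export
add_noise <- function(img, cfg, seed = cfg$seed) {
  if (cfg$noise_sd < 0) stop_param("noise_sd must be >= 0")
  if (cfg$noise_sd == 0) return(img)
  px <- as_pixels(img)
  withr::with_seed(derive_seed(seed, "add_noise"), {
    noise <- matrix(stats::rnorm(length(px), 0, cfg$noise_sd),
                    nrow(px), ncol(px))
  })
  if (inherits(img, "field_image")) {
    img$pixels <- px + noise
    img
  } else {
    px + noise
  }
}

#' Render a multi-neuron section: marker channel, probe channel and masks
#'
#' Places the somata of `neurons` as non-overlapping disks in a square
#' field, renders the requested probe's puncta (each neuron's
#' `true_puncta_<probe>` emitters, uniform inside its soma, weighted by its
#' `eps_mult_<probe>`) through the PSF with additive noise, and renders the
#' marker channel as filled disks for neurons of `marker`. Ground-truth
#' label masks are returned for oracle use.
#'
#' @param neurons a `neuron_population` (rows to render).
#' @param cfg a [sim_config()].
#' @param probe probe whose puncta channel to render.
#' @param marker marker whose soma channel to render (default: all rows).
#' @param field_um field side length, um; sized automatically if `NULL`.
#' @param marker_value intensity of marker-channel disks, i.u.
#' @param max_tries placement retries before giving up.
#' @param seed integer seed.
#' @return list with `probe_img`, `marker_img` (field_images), `masks`
#'   (integer label matrix, 0 = background, i = neuron i), and `placement`
#'   (data.frame id, row_px, col_px, radius_px).
#' @export
render_section <- function(neurons, cfg, probe, marker = NULL,
                           field_um = NULL, marker_value = 100,
                           max_tries = 2000, seed = cfg$seed) {
  validate_sim_config(cfg)
  px_um <- cfg$pixel_size / 1000
  radius_um <- sqrt(neurons$soma_area / pi)
  if (is.null(field_um)) {
    # ~3x the summed soma area gives room for non-overlapping placement
    field_um <- max(4 * max(radius_um), sqrt(3 * sum(neurons$soma_area)))
  }
  npx <- ceiling(field_um / px_um)
  radius_px <- radius_um / px_um
  n <- nrow(neurons)
  placement <- data.frame(id = neurons$id, row_px = NA_real_,
                          col_px = NA_real_, radius_px = radius_px)
  withr::with_seed(derive_seed(seed, "render_section"), {
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        r0 <- stats::runif(1, radius_px[i] + 1, npx - radius_px[i])
        c0 <- stats::runif(1, radius_px[i] + 1, npx - radius_px[i])
        prev <- seq_len(i - 1L)
        if (i == 1L ||
            all((placement$row_px[prev] - r0)^2 +
                (placement$col_px[prev] - c0)^2 >
                (placement$radius_px[prev] + radius_px[i])^2)) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop_param(paste0("could not place %d non-overlapping somata in a ",
                          "%.0f-um field; increase field_um"), n, field_um)
      placement$row_px[i] <- r0
      placement$col_px[i] <- c0
    }
    # puncta: uniform in each soma disk, weighted by the cell's multiplier
    counts <- matrix(0, npx, npx)
    tp <- neurons[[paste0("true_puncta_", probe)]]
    em <- neurons[[paste0("eps_mult_", probe)]] %||% rep(1, n)
    for (i in seq_len(n)) {
      k <- tp[i]
      if (k == 0) next
      rad <- radius_px[i] * sqrt(stats::runif(k))
      th <- stats::runif(k, 0, 2 * pi)
      row <- pmin(pmax(floor(placement$row_px[i] + rad * sin(th)) + 0L, 1L), npx)
      col <- pmin(pmax(floor(placement$col_px[i] + rad * cos(th)) + 0L, 1L), npx)
      for (j in seq_len(k)) counts[row[j], col[j]] <- counts[row[j], col[j]] + em[i]
    }
  })
  probe_img <- psf_render(counts, cfg, channel = probe)
  probe_img <- add_noise(probe_img, cfg, seed = derive_seed(seed, "section_noise"))
  pad <- probe_img$pad_px
  dim_out <- npx + 2L * pad
  masks <- matrix(0L, dim_out, dim_out)
  marker_px <- matrix(0, dim_out, dim_out)
  sel <- if (is.null(marker)) rep(TRUE, n) else neurons$marker == marker
  for (i in seq_len(n)) {
    m <- disk_mask(dim_out, dim_out, placement$row_px[i] + pad,
                   placement$col_px[i] + pad, radius_px[i])
    masks[m] <- i
    if (sel[i]) marker_px[m] <- marker_value
  }
  placement$row_px <- placement$row_px + pad
  placement$col_px <- placement$col_px + pad
  list(
    probe_img = probe_img,
    marker_img = field_image(marker_px, cfg$pixel_size, pad_px = pad,
                             channel = marker %||% "all-markers"),
    masks = masks,
    placement = placement
  )
}

#' Write / read a field image as 32-bit float TIFF with a JSON sidecar
#'
#' TIFF float samples must lie in \[0, 1\], so pixels are stored
#' affine-normalized; the original range, pixel size, channel and
#' provenance go in `<path>.json` and reading restores the intensity
#' scale (to 32-bit float precision).
#' @param img a `field_image`.
#' @param path output TIFF path.
#' @return `path` (write); a `field_image` (read).
#' @export
write_field_tiff <- function(img, path) {
  stopifnot(inherits(img, "field_image"))
  lo <- min(img$pixels)
  hi <- max(img$pixels)
  span <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((img$pixels - lo) / span, path, bits.per.sample = 32L,
                  reduce = FALSE)
  jsonlite::write_json(
    list(pixel_size_nm = img$pixel_size, pad_px = img$pad_px,
         channel = img$channel, intensity_min = lo, intensity_max = hi,
         meta = img$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  px <- tiff::readTIFF(path, as.is = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lo <- side$intensity_min %||% 0
  hi <- side$intensity_max %||% 1
  span <- if (hi > lo) hi - lo else 1
  field_image(px * span + lo, side$pixel_size_nm,
              pad_px = side$pad_px %||% 0L,
              channel = side$channel %||% "probe",
              meta = as.list(side$meta %||% list()))
}
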