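#' Detect puncta as thresholded local maxima with minimum separation
#'
#' A pixel is a candidate peak when its amplitude exceeds `threshold` and is
#' a local maximum over its 8-neighborhood. Equal-valued neighboring maxima
#' (plateaus) are resolved deterministically by keeping the
#' lexicographically smallest pixel (row, then column). Candidates are then
#' greedily suppressed in order of decreasing amplitude: a candidate closer
#' than `min_separation` (Euclidean, pixels) to an already-kept peak is
#' dropped. The default separation is the PSF e^-2 radius in pixels,
#' mirroring the rule that two detected peaks cannot be closer than omega0.
#'
#' @param img a `field_image` or numeric matrix.
#' @param threshold amplitude threshold, i.u. (> 0).
#' @param min_separation minimum peak separation, pixels (>= 1 by default
#'   semantics; fractional values such as 1.5 px are allowed).
#' @return a `spot_set`: data.frame with columns `row`, `col`, `x`, `y`
#'   (x = col, y = row) and `amplitude`, with attributes `threshold`,
#'   `min_separation` and `channel`.
#' @export
detect_peaks <- function(img, threshold = 6, min_separation = 1.5) {
  px <- as_pixels(img)
  if (any(!is.finite(px))) stop_param("image contains non-finite pixels")
  if (threshold <= 0) stop_param("threshold must be > 0")
  if (min_separation < 0) stop_param("min_separation must be >= 0")
  nr <- nrow(px); nc <- ncol(px)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- px
  keep <- px > threshold
  # shifts (dr, dc); a tie is allowed only against a lexicographically
  # later neighbor, which leaves one representative per plateau
  for (sh in list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                  c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))) {
    nb <- pad[2:(nr + 1L) + sh[1], 2:(nc + 1L) + sh[2]]
    later <- sh[1] > 0L || (sh[1] == 0L && sh[2] > 0L)
    keep <- keep & (if (later) px >= nb else px > nb)
  }
  idx <- which(keep, arr.ind = TRUE)
  cand <- data.frame(row = idx[, 1], col = idx[, 2],
                     amplitude = px[idx])
  if (nrow(cand)) {
    tied <- vapply(seq_len(nrow(cand)), function(i) {
      r <- cand$row[i]; c <- cand$col[i]
      sum(pad[r:(r + 2L), c:(c + 2L)] == cand$amplitude[i]) > 1L
    }, logical(1))
    if (any(tied)) {
      ok <- vapply(which(tied), function(i) {
        plateau_is_maximum(px, cand$row[i], cand$col[i])
      }, logical(1))
      drop <- which(tied)[!ok]
      if (length(drop)) cand <- cand[-drop, , drop = FALSE]
    }
  }
  kept <- greedy_suppress(cand, min_separation)
  spot_set(kept, threshold, min_separation,
           channel = if (inherits(img, "field_image")) img$channel else NA)
}

# For a candidate lying on an equal-valued plateau: flood-fill the plateau
# (8-connected) and require (a) the candidate is its lexicographic minimum
# and (b) every pixel bordering the plateau is strictly lower. A plateau
# with no border (the whole image) is not a maximum.
plateau_is_maximum <- function(px, r0, c0) {
  nr <- nrow(px); nc <- ncol(px)
  v <- px[r0, c0]
  seen <- matrix(FALSE, nr, nc)
  queue <- list(c(r0, c0))
  seen[r0, c0] <- TRUE
  border <- 0L
  while (length(queue)) {
    cur <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- cur[1] + dr; cc <- cur[2] + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (seen[rr, cc]) next
      if (px[rr, cc] == v) {
        if (rr < r0 || (rr == r0 && cc < c0)) return(FALSE)
        seen[rr, cc] <- TRUE
        queue[[length(queue) + 1L]] <- c(rr, cc)
      } else {
        if (px[rr, cc] > v) return(FALSE)
        border <- border + 1L
      }
    }
  }
  border > 0L
}

# Greedy minimum-separation suppression, highest amplitude first; ties by
# (row, col). Normative semantics, locked by a brute-force oracle test.
greedy_suppress <- function(cand, min_separation) {
  if (nrow(cand) == 0) return(cand)
  ord <- order(-cand$amplitude, cand$row, cand$col)
  cand <- cand[ord, , drop = FALSE]
  kept <- logical(nrow(cand))
  kr <- numeric(0); kc <- numeric(0)
  min2 <- min_separation^2
  for (i in seq_len(nrow(cand))) {
    if (length(kr) == 0 ||
        all((kr - cand$row[i])^2 + (kc - cand$col[i])^2 >= min2)) {
      kept[i] <- TRUE
      kr <- c(kr, cand$row[i]); kc <- c(kc, cand$col[i])
    }
  }
  out <- cand[kept, , drop = FALSE]
  out[order(out$row, out$col), , drop = FALSE]
}

spot_set <- function(df, threshold, min_separation, channel = NA) {
  df$x <- df$col
  df$y <- df$row
  rownames(df) <- NULL
  structure(df[, c("row", "col", "x", "y", "amplitude")],
            threshold = threshold, min_separation = min_separation,
            channel = channel, class = c("spot_set", "data.frame"))
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set> %d peaks (threshold %g, min separation %g px)\n",
              nrow(x), attr(x, "threshold"), attr(x, "min_separation")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Count detected puncta inside a mask
#'
#' @param spots a `spot_set`.
#' @param mask logical (or 0/1) matrix in the same pixel frame as the
#'   detection image.
#' @return integer count of peaks whose pixel lies inside the mask.
#' @export
count_puncta_in_roi <- function(spots, mask) {
  if (nrow(spots) == 0) return(0L)
  mask <- mask != 0
  inside <- mask[cbind(spots$row, spots$col)]
  sum(inside)
}

#' Serialize a spot set as CSV
#' @param spots a `spot_set`.
#' @param path file path.
#' @export
write_spots_csv <- function(spots, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# punctasim spots; threshold=%g; min_separation=%g",
                     attr(spots, "threshold"), attr(spots, "min_separation")),
             con)
  utils::write.csv(data.frame(x_px = spots$x, y_px = spots$y,
                              amplitude = spots$amplitude),
                   con, row.names = FALSE)
  invisible(path)
}

#' Density sweep: detected puncta versus true puncta density
#'
#' For each density, runs `reps` seeded simulate-render-detect cycles on
#' the circular ROI and averages the true emitter count, the detected peak
#' count and the total image intensity. At low densities every isolated
#' emitter is resolved, so detected ~ true; as density rises, peaks merge
#' under the PSF and the minimum-separation rule, so the detected count
#' saturates while total intensity keeps scaling linearly with the true
#' count.
#'
#' @param cfg a [sim_config()]; its `density` field is overridden.
#' @param densities puncta per um^2 (the reference sweep spans 0.0001 to
#'   3.1).
#' @param reps replicates per density.
#' @param seed integer master seed.
#' @return data.frame with one row per density: `density`, `mean_true_n`,
#'   `mean_detected_n`, `detected_true_ratio` (pooled
#'   `sum(detected)/sum(true)` over replicates with at least one emitter),
#'   `mean_total_intensity` (image sum, whose expectation is unaffected by
#'   the zero-mean noise).
#' @export
saturation_experiment <- function(cfg = sim_config(),
                                  densities = c(0.0001, 0.001, 0.01, 0.05,
                                                0.1, 0.31, 1, 3.1),
                                  reps = 100, seed = cfg$seed) {
  if (reps < 1) stop_param("reps must be >= 1")
  if (any(densities < 0)) stop_param("densities must be >= 0")
  min_sep <- omega0_px(cfg)
  out <- lapply(seq_along(densities), function(di) {
    d <- densities[di]
    cfg_d <- cfg
    cfg_d$density <- d
    true_n <- detected_n <- total_i <- numeric(reps)
    for (r in seq_len(reps)) {
      s <- derive_seed(seed, sprintf("saturation_%g_%d", d, r))
      pos <- place_emitters(cfg_d, seed = s)
      counts <- render_counts(pos, cfg_d)
      img <- psf_render(counts, cfg_d)
      img <- add_noise(img, cfg_d, seed = s)
      spots <- detect_peaks(img, threshold = cfg_d$detect_threshold,
                            min_separation = min_sep)
      true_n[r] <- nrow(pos)
      detected_n[r] <- nrow(spots)
      total_i[r] <- sum(img$pixels)
    }
    data.frame(
      density = d,
      mean_true_n = mean(true_n),
      mean_detected_n = mean(detected_n),
      detected_true_ratio = if (sum(true_n) > 0)
        sum(detected_n) / sum(true_n) else NA_real_,
      mean_total_intensity = mean(total_i)
    )
  })
  do.call(rbind, out)
}
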