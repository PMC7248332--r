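# Independent reference implementations used as oracles. Deliberately
# naive (explicit loops, sqrt distances) so they share no code with the
# package's vectorized paths.

# Exhaustive 8-neighborhood local-maxima scan with the lexicographic
# plateau tie-break: a pixel is kept when it beats every neighbor, allowing
# a tie only against neighbors that come later in (row, col) order.
brute_force_candidates <- function(px, threshold) {
  nr <- nrow(px); nc <- ncol(px)
  out <- NULL
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      v <- px[r, c]
      if (v <= threshold) next
      ok <- TRUE
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- r + dr; cc <- c + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          nb <- px[rr, cc]
          later <- dr > 0 || (dr == 0 && dc > 0)
          if (if (later) v < nb else v <= nb) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) out <- rbind(out, data.frame(row = r, col = c, amplitude = v))
    }
  }
  if (is.null(out)) data.frame(row = integer(0), col = integer(0),
                               amplitude = numeric(0)) else out
}

# Keep-highest-first suppression: no two kept peaks closer than min_sep.
brute_force_suppress <- function(cand, min_sep) {
  if (nrow(cand) == 0) return(cand)
  cand <- cand[order(-cand$amplitude, cand$row, cand$col), , drop = FALSE]
  kept <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in seq_len(nrow(kept))) {
      d <- sqrt((kept$row[j] - cand$row[i])^2 +
                (kept$col[j] - cand$col[i])^2)
      if (d < min_sep) { ok <- FALSE; break }
    }
    if (ok) kept <- rbind(kept, cand[i, ])
  }
  kept[order(kept$row, kept$col), c("row", "col", "amplitude")]
}

brute_force_detect <- function(px, threshold, min_sep) {
  brute_force_suppress(brute_force_candidates(px, threshold), min_sep)
}

# Render emitters given directly in pixel coordinates of the count grid.
render_emitters_px <- function(coords, cfg, dim = 64L) {
  counts <- matrix(0, dim, dim)
  for (i in seq_len(nrow(coords))) {
    counts[coords[i, 1], coords[i, 2]] <- counts[coords[i, 1], coords[i, 2]] + 1
  }
  psf_render(counts, cfg)
}

# A small single-class Bernoulli population for end-to-end checks.
single_class_params <- function(marker, probe = "ASIC3", p_expr = 0.5) {
  mp <- c(NF200 = 0, CGRP = 0, IB4 = 0, unlabeled = 0)
  mp[marker] <- 1
  ep <- matrix(p_expr, nrow = 4, ncol = 1,
               dimnames = list(names(mp), probe))
  population_params(probes = probe, mode = "bernoulli",
                    marker_proportions = mp, expr_prob = ep)
}
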