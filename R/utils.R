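# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a stream label so
# that each stochastic stage draws from its own independent stream.
# Stays below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (code in utf8ToInt(as.character(stream))) {
    h <- (h * 131 + code) %% 2147483647
  }
  a <- abs(seed) %% 2147483647
  as.integer(((a * 48271) %% 2147483647 + h) %% 2147483629 + 1)
}

# Rasterize a filled disk: logical matrix marking pixels whose centers lie
# within `radius_px` of (row0, col0) (both in pixel units, may be fractional).
disk_mask <- function(nrow, ncol, row0, col0, radius_px) {
  rr <- matrix(seq_len(nrow), nrow, ncol) - row0
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE) - col0
  rr * rr + cc * cc <= radius_px * radius_px
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
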